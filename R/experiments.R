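#' Gain-recovery experiment on a synthetic session
#'
#' Builds a reduced synthetic session in which each performance type
#' carries one amplitude gain from `gains` in every window of `band`,
#' runs the full signal path (broadband filter, epoching, artifact
#' mask, Hilbert band power, group baseline, index, per-cell average)
#' and compares the recovered ERD/ERS index per (channel, window, gain)
#' cell with the injected ground truth `100 * (1 - g^2)`.
#'
#' @param gains Four amplitude gains, one per performance type.
#' @param band Band the gains are injected into (others stay at 1).
#' @param n_subjects,n_trials,fs,channels,inter_shot_mean Reduced
#'   session geometry; the defaults trade the full study size for
#'   runtime while keeping at least ~50 epochs per type.
#' @param seed Integer seed.
#' @return Data frame per (subject, type, gain, channel, window):
#'   `recovered` (mean index over the cell's epochs), `expected`, and
#'   `error = recovered - expected`.
#' @export
recovery_experiment <- function(gains = c(0.6, 0.8, 1.0, 1.25),
                                band = "low_alpha",
                                n_subjects = 1, n_trials = 240,
                                fs = 256,
                                channels = c("Fz", "Cz", "C3", "C4"),
                                inter_shot_mean = 14, seed = 1L) {
  stopifnot(length(gains) == 4L)
  gain_table <- data.frame(type = performance_types(), band = band,
                           window = "all", channel = "all", gain = gains,
                           stringsAsFactors = FALSE)
  cfg <- simulation_config(
    n_subjects = n_subjects, n_trials = n_trials, fs = fs,
    channels = channels, inter_shot_mean = inter_shot_mean,
    inter_shot_jitter = 1, amplitude_gain = gain_table,
    artifact_rate = 0,
    quadrant_mix = stats::setNames(rep(0.25, 4), performance_types()),
    seed = seed)
  session <- simulate_session(cfg)
  out <- list()
  for (rec in session$recordings) {
    filtered <- bandpass_broad(rec)
    epochs <- epoch_extract(filtered, session$events)
    epochs <- artifact_detect(epochs)
    key <- paste(epochs$trials$subject, epochs$trials$trial)
    beh <- session$behavior
    types <- beh$type[match(key, paste(beh$subject, beh$trial))]
    maps <- compute_erders(epochs, types,
                           bands = default_bands()[
                             default_bands()$name == band, ])
    for (e in maps$entries) {
      g <- gains[match(e$type, performance_types())]
      out[[length(out) + 1L]] <- data.frame(
        subject = e$subject, type = e$type, gain = g,
        channel = rep(rownames(e$index), ncol(e$index)),
        window = rep(seq_len(ncol(e$index)), each = nrow(e$index)),
        recovered = as.vector(e$index),
        expected = 100 * (1 - g^2), n_epochs = e$n,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$error <- res$recovered - res$expected
  res
}

#' Null ERD/ERS index tables for calibration simulations
#'
#' Draws per-trial index values with no quadrant or interval effect
#' (i.i.d. Gaussian around 0, emulating index noise of an unmodulated
#' session) and reduces them to the subject x type x interval cell
#' means that enter the ANOVA, mirroring the pipeline's reduction step.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_cell Trials behind each (subject, type) cell.
#' @param sd Per-trial index standard deviation (percent points).
#' @return Array subjects x 4 x 3 of cell means.
#' @export
null_index_table <- function(n_subjects = 10, n_trials_per_cell = 20,
                             sd = 15) {
  cells <- array(0, dim = c(n_subjects, 4, 3))
  for (s in seq_len(n_subjects)) for (a in 1:4) for (b in 1:3) {
    cells[s, a, b] <- mean(stats::rnorm(n_trials_per_cell, 0, sd))
  }
  cells
}

#' Type-I error calibration of the ANOVA battery
#'
#' Runs [rm_anova()] on `n_rep` independent null index tables and
#' returns the per-effect rejection rate at `alpha` under the chosen
#' sphericity-correction policy.
#'
#' @param n_rep Number of simulated datasets.
#' @param n_subjects,n_trials_per_cell,sd Passed to
#'   [null_index_table()].
#' @param alpha Nominal level.
#' @param correction Passed to [rm_anova()].
#' @param seed Integer seed.
#' @return Named numeric: rejection rate for the performance, time and
#'   interaction effects, plus `overall` (all effects pooled).
#' @export
type1_error_rate <- function(n_rep = 500, n_subjects = 10,
                             n_trials_per_cell = 20, sd = 15,
                             alpha = 0.05,
                             correction = "mauchly-gated", seed = 1L) {
  set.seed(as.integer(seed))
  rej <- matrix(FALSE, n_rep, 3,
                dimnames = list(NULL, c("A", "B", "A:B")))
  for (r in seq_len(n_rep)) {
    cells <- null_index_table(n_subjects, n_trials_per_cell, sd)
    an <- rm_anova(cells, correction = correction)
    rej[r, ] <- an$p_corrected < alpha
  }
  rates <- colMeans(rej)
  c(performance = unname(rates["A"]), time = unname(rates["B"]),
    interaction = unname(rates["A:B"]), overall = mean(rej))
}
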
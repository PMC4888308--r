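#' Configuration for a synthetic shooting-session recording
#'
#' Defines the study conditions emulated by the generator: continuous
#' multichannel EEG around self-paced air-pistol shots, with per-band
#' oscillations whose amplitude is multiplied by a configurable gain
#' inside designated 1-s pre-shot windows, a 1/f^alpha Gaussian
#' background, occasional ocular/muscular transients, and per-trial
#' behaviour (shooting score 0-10.9, perceived control 0-11) drawn per
#' MAP quadrant. Defaults reproduce the recording setup of the study the
#' pipeline targets: 10 subjects, 120 trials each, 1024 Hz, the
#' 32-channel 10-20 cap, and roughly one shot per minute.
#'
#' Amplitude gains act on oscillation *amplitude*; the ground-truth
#' ERD/ERS index is expressed in *power*, i.e. `100 * (1 - g^2)` percent,
#' so a gain below 1 yields a positive (ERD) index. This is stated
#' explicitly to avoid the classic factor-of-two confusion between
#' amplitude and power modulation.
#'
#' @param n_subjects,n_trials Counts of subjects and shots per subject.
#' @param fs Sampling frequency, Hz. Must exceed twice the highest band
#'   edge (and in practice twice the broadband filter edge of 40 Hz).
#' @param channels Channel labels; must be sites of [montage_1020()].
#' @param inter_shot_mean,inter_shot_jitter Mean and uniform half-width
#'   of the inter-shot interval, seconds. The minimum interval must leave
#'   room for a full -6..+4 s epoch.
#' @param band_freqs Named centre frequency (Hz) of the oscillator that
#'   carries each band's power.
#' @param osc_amplitude Named oscillation amplitude per band, uV.
#' @param amplitude_gain Data frame with columns `type`, `band`,
#'   `window` (1:3 or `"all"`), `channel` (a label or `"all"`), `gain`;
#'   rows give the amplitude gain applied in that pre-shot window for
#'   trials of that performance type. Omitted cells default to gain 1
#'   (no modulation); channel-specific rows override `"all"` rows.
#' @param noise_sd Standard deviation of the 1/f background, uV.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param artifact_rate Ocular/muscular transients per minute.
#' @param quadrant_mix Named probability of each performance type per
#'   trial; must sum to 1. Default is the empirical mix of the study's
#'   1148 retained shots.
#' @param behavior_params Per-type list of `score_mean`, `score_sd`,
#'   `control_mean`, `control_sd`; defaults follow the study's
#'   descriptive table. Draws are truncated to the quadrant's region
#'   under `rule` so that categorization recovers the generating type.
#' @param rule Quadrant rule (see [quadrant_rule()]) defining the regions
#'   behaviour is truncated to.
#' @param subject_gain_sd Half-width of the uniform per-subject,
#'   per-channel oscillation-amplitude heterogeneity (0.1 = +/-10%).
#' @param phase_drift_sd Per-sample standard deviation of the slow random
#'   phase drift of each oscillator, radians.
#' @param ramp_s Raised-cosine transition length at modulation window
#'   edges, seconds; avoids broadband splatter from step modulation.
#' @param pre_margin,post_margin Recording margin before the first and
#'   after the last shot, seconds.
#' @param windows Analysis windows ([analysis_windows()]); modulation
#'   windows are its `intervals`.
#' @param seed Integer seed making the session reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 10,
                              n_trials = 120,
                              fs = 1024,
                              channels = waveguard32_labels(),
                              inter_shot_mean = 60,
                              inter_shot_jitter = 5,
                              band_freqs = c(theta = 6, low_alpha = 9,
                                             high_alpha = 11),
                              osc_amplitude = c(theta = 10, low_alpha = 10,
                                                high_alpha = 10),
                              amplitude_gain = default_gain_table(),
                              noise_sd = 3,
                              noise_exponent = 1,
                              artifact_rate = 1,
                              quadrant_mix = c(Type1 = 238, Type2 = 350,
                                               Type3 = 212, Type4 = 348) / 1148,
                              behavior_params = default_behavior_params(),
                              rule = quadrant_rule(),
                              subject_gain_sd = 0.1,
                              phase_drift_sd = 0.01,
                              ramp_s = 0.1,
                              pre_margin = 8,
                              post_margin = 6,
                              windows = analysis_windows(),
                              seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials), fs = fs,
              channels = channels,
              inter_shot_mean = inter_shot_mean,
              inter_shot_jitter = inter_shot_jitter,
              band_freqs = band_freqs, osc_amplitude = osc_amplitude,
              amplitude_gain = amplitude_gain,
              noise_sd = noise_sd, noise_exponent = noise_exponent,
              artifact_rate = artifact_rate, quadrant_mix = quadrant_mix,
              behavior_params = behavior_params, rule = rule,
              subject_gain_sd = subject_gain_sd,
              phase_drift_sd = phase_drift_sd, ramp_s = ramp_s,
              pre_margin = pre_margin, post_margin = post_margin,
              windows = windows, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_subjects < 1L || cfg$n_trials < 1L)
    stop("configuration error: need at least one subject and one trial")
  if (cfg$fs <= 2 * max(cfg$band_freqs) || cfg$fs <= 2 * 12)
    stop("configuration error: fs must exceed twice the highest band edge")
  montage_1020(cfg$channels)  # errors on unknown labels
  if (anyDuplicated(cfg$channels))
    stop("configuration error: duplicated channel labels")
  if (any(cfg$amplitude_gain$gain <= 0))
    stop("configuration error: amplitude gains must be > 0")
  if (abs(sum(cfg$quadrant_mix) - 1) > 1e-8)
    stop("configuration error: quadrant_mix must sum to 1")
  if (!setequal(names(cfg$quadrant_mix), performance_types()))
    stop("configuration error: quadrant_mix must name the four types")
  min_gap <- cfg$inter_shot_mean - cfg$inter_shot_jitter
  if (min_gap < 10.5)
    stop("configuration error: inter-shot interval too short for a ",
         "-6..+4 s epoch per shot (need >= 10.5 s)")
  if (cfg$pre_margin < 6.5 || cfg$post_margin < 4.5)
    stop("configuration error: recording margins too small for epoching")
  invisible(cfg)
}

#' @rdname simulation_config
#' @export
default_gain_table <- function() {
  # Direction of the injected effects: alpha synchronization (g > 1) for
  # the automatic states (Types 1 and 4), alpha desynchronization (g < 1)
  # for the controlled states (Types 2 and 3, strongest in Type 3), and a
  # theta ERD confined to Type 3. Magnitudes are the generator's own
  # choice; only the direction mirrors the reported topographies.
  g <- rbind(
    data.frame(type = "Type1", band = c("theta", "low_alpha", "high_alpha"),
               gain = c(1.10, 1.15, 1.15)),
    data.frame(type = "Type2", band = c("theta", "low_alpha", "high_alpha"),
               gain = c(1.05, 0.85, 0.85)),
    data.frame(type = "Type3", band = c("theta", "low_alpha", "high_alpha"),
               gain = c(0.85, 0.80, 0.80)),
    data.frame(type = "Type4", band = c("theta", "low_alpha", "high_alpha"),
               gain = c(1.10, 1.10, 1.10)))
  g$window <- "all"
  g$channel <- "all"
  g[, c("type", "band", "window", "channel", "gain")]
}

#' @rdname simulation_config
#' @export
default_behavior_params <- function() {
  # Means/SDs of score and perceived control per performance type follow
  # the study's descriptive table of the 1148 retained shots.
  list(Type1 = list(score_mean = 10.51, score_sd = 0.12,
                    control_mean = 4.59, control_sd = 0.39),
       Type2 = list(score_mean = 10.45, score_sd = 0.12,
                    control_mean = 6.47, control_sd = 0.54),
       Type3 = list(score_mean = 9.90, score_sd = 0.19,
                    control_mean = 6.44, control_sd = 0.46),
       Type4 = list(score_mean = 9.76, score_sd = 0.24,
                    control_mean = 4.39, control_sd = 0.54))
}

# Gain lookup: channel-specific rows override "all"; window-specific rows
# override "all"; absent -> 1.
lookup_gain <- function(gain_table, type, band, window_idx, channel) {
  g <- gain_table[gain_table$type == type & gain_table$band == band, ,
                  drop = FALSE]
  if (nrow(g) == 0L) return(1)
  g <- g[g$window == "all" | g$window == as.character(window_idx), ,
         drop = FALSE]
  if (nrow(g) == 0L) return(1)
  spec <- g[g$channel == channel, , drop = FALSE]
  if (nrow(spec) > 0L) return(spec$gain[[1L]])
  all_ch <- g[g$channel == "all", , drop = FALSE]
  if (nrow(all_ch) > 0L) return(all_ch$gain[[1L]])
  1
}

#' Draw per-trial performance types from the configured quadrant mixture
#'
#' @param config A [simulation_config()].
#' @param n Number of trials.
#' @param seed Optional integer seed (`NULL` continues the RNG stream).
#' @return Character vector of performance types.
#' @export
draw_quadrants <- function(config, n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sample(names(config$quadrant_mix), n, replace = TRUE,
         prob = config$quadrant_mix)
}

# Truncated-normal sampler by inverse-CDF; sd = 0 degenerates to the mean.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(hi, pmax(lo, stats::qnorm(u, mean, sd)))
}

#' Draw per-trial behaviour for given performance quadrants
#'
#' Scores and perceived-control ratings are drawn from normal
#' distributions with the configured per-quadrant means/SDs, truncated to
#' the quadrant's region under the configured rule (optimal scores in
#' \[score_threshold, 10.9\], automatic control in \[0, control_threshold\],
#' and so on), so that fixed-rule categorization recovers the generating
#' quadrant for every trial.
#'
#' @param config A [simulation_config()].
#' @param quadrants Character vector of performance types, one per trial.
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @param subject_id Subject identifier attached to the rows.
#' @return Data frame `subject`, `trial`, `score`, `control`, `type`.
#' @export
simulate_behavior <- function(config, quadrants, seed = NULL,
                              subject_id = "S01") {
  if (length(quadrants) == 0L) stop("input error: empty quadrant list")
  stopifnot(all(quadrants %in% performance_types()))
  if (!is.null(seed)) set.seed(as.integer(seed))
  sth <- config$rule$score_threshold
  cth <- config$rule$control_threshold
  eps <- 1e-6
  n <- length(quadrants)
  score <- control <- numeric(n)
  for (ty in unique(quadrants)) {
    idx <- which(quadrants == ty)
    p <- config$behavior_params[[ty]]
    optimal <- ty %in% c("Type1", "Type2")
    automatic <- ty %in% c("Type1", "Type4")
    s_lo <- if (optimal) sth else 0
    s_hi <- if (optimal) 10.9 else sth - eps
    c_lo <- if (automatic) 0 else cth + eps
    c_hi <- if (automatic) cth else 11
    score[idx] <- rtrunc_norm(length(idx), p$score_mean, p$score_sd,
                              s_lo, s_hi)
    control[idx] <- rtrunc_norm(length(idx), p$control_mean, p$control_sd,
                                c_lo, c_hi)
  }
  data.frame(subject = subject_id, trial = seq_len(n),
             score = score, control = control, type = quadrants,
             stringsAsFactors = FALSE)
}

# 1/f^alpha Gaussian background via spectral shaping, rescaled to sd.
pink_noise <- function(n, alpha, sd) {
  if (sd <= 0) return(numeric(n))
  nfft <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(nfft)
  spec <- stats::fft(white)
  f <- c(1e-12, seq_len(nfft - 1))  # kill DC, shape the rest
  f <- pmin(f, nfft - f + 1)        # symmetric in frequency index
  shape <- f^(-alpha / 2)
  shape[1] <- 0
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x * sd / stats::sd(x)
}

# Smoothed per-sample amplitude envelope for one (band, channel): 1
# outside modulation windows, gain inside, raised-cosine transitions.
modulation_envelope <- function(n, fs, onsets_s, types, gains_by_trial,
                                intervals, ramp_s) {
  env <- rep(1, n)
  half <- ramp_s / 2
  for (i in seq_along(onsets_s)) {
    g <- gains_by_trial[[i]]
    for (w in seq_along(intervals)) {
      if (g[w] == 1) next
      iv <- intervals[[w]]
      a <- max(1L, round((onsets_s[i] + iv[1] - half) * fs) + 1L)
      b <- min(n, round((onsets_s[i] + iv[2] + half) * fs))
      env[a:b] <- g[w]
    }
  }
  L <- max(3L, round(ramp_s * fs))
  if (L %% 2L == 0L) L <- L + 1L
  kern <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  kern <- kern / sum(kern)
  padded <- c(rep(env[1], L), env, rep(env[n], L))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(L + 1):(L + n)])
}

#' Generate a full synthetic shooting session
#'
#' Produces, for every subject, a continuous EEG recording in which each
#' band's oscillation amplitude is multiplied by the configured gain
#' inside each designated pre-shot window of each trial (and equals the
#' baseline amplitude inside -5..-4 s), plus the shot-event table,
#' per-trial behaviour, the injected-artifact log, and the ground-truth
#' table of expected ERD/ERS indices `100 * (1 - g^2)` that the analysis
#' stages must recover. Identical `(config, seed)` pairs reproduce
#' identical output.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return List with elements `recordings` (list of [eeg_recording()] per
#'   subject), `events` (subject, trial, onset_s), `behavior`,
#'   `ground_truth` (subject, trial, type, band, window, channel, gain,
#'   expected_index) and `artifact_log`.
#' @export
simulate_session <- function(config, seed = NULL) {
  validate_simulation_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(seed)
  fs <- config$fs
  bands <- names(config$band_freqs)
  intervals <- config$windows$intervals
  types <- performance_types()

  recordings <- vector("list", config$n_subjects)
  events <- behavior <- gt <- art <- list()

  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    quadrants <- draw_quadrants(config, config$n_trials)
    beh <- simulate_behavior(config, quadrants, seed = NULL,
                             subject_id = sid)
    gaps <- config$inter_shot_mean +
      stats::runif(config$n_trials, -config$inter_shot_jitter,
                   config$inter_shot_jitter)
    onsets <- config$pre_margin + cumsum(gaps) - gaps[1] + 0
    onsets <- onsets - min(onsets) + config$pre_margin
    duration <- max(onsets) + config$post_margin
    n <- round(duration * fs)

    # Per-trial gain vectors per band (one gain per interval window).
    gains <- lapply(bands, function(bd) {
      lapply(seq_len(config$n_trials), function(i) {
        vapply(seq_along(intervals), function(w) {
          lookup_gain(config$amplitude_gain, quadrants[i], bd, w, "all")
        }, numeric(1))
      })
    })
    names(gains) <- bands

    chan_specific <- any(config$amplitude_gain$channel != "all")
    env_shared <- if (!chan_specific) {
      lapply(bands, function(bd) {
        modulation_envelope(n, fs, onsets, quadrants, gains[[bd]],
                            intervals, config$ramp_s)
      })
    }
    if (!chan_specific) names(env_shared) <- bands

    het <- matrix(stats::runif(length(config$channels) * length(bands),
                               1 - config$subject_gain_sd,
                               1 + config$subject_gain_sd),
                  nrow = length(config$channels),
                  dimnames = list(config$channels, bands))

    t_vec <- seq_len(n) / fs
    data <- matrix(0, nrow = length(config$channels), ncol = n,
                   dimnames = list(config$channels, NULL))
    for (ci in seq_along(config$channels)) {
      ch <- config$channels[ci]
      x <- pink_noise(n, config$noise_exponent, config$noise_sd)
      for (bd in bands) {
        env <- if (chan_specific) {
          g_ch <- lapply(seq_len(config$n_trials), function(i) {
            vapply(seq_along(intervals), function(w) {
              lookup_gain(config$amplitude_gain, quadrants[i], bd, w, ch)
            }, numeric(1))
          })
          modulation_envelope(n, fs, onsets, quadrants, g_ch,
                              intervals, config$ramp_s)
        } else env_shared[[bd]]
        drift <- cumsum(stats::rnorm(n, 0, config$phase_drift_sd))
        phi0 <- stats::runif(1, 0, 2 * pi)
        a <- config$osc_amplitude[[bd]] * het[ci, bd]
        x <- x + a * env *
          sin(2 * pi * config$band_freqs[[bd]] * t_vec + phi0 + drift)
      }
      data[ci, ] <- x
    }

    rec <- eeg_recording(data, fs, config$channels, subject_id = sid)
    if (config$artifact_rate > 0) {
      inj <- inject_artifacts(rec, config$artifact_rate, seed = NULL)
      rec <- inj$recording
      if (nrow(inj$artifact_log) > 0L) art[[sid]] <- inj$artifact_log
    }
    recordings[[s]] <- rec
    events[[sid]] <- data.frame(subject = sid,
                                trial = seq_len(config$n_trials),
                                onset_s = onsets, stringsAsFactors = FALSE)
    behavior[[sid]] <- beh

    # Ground truth: one row per (trial, band, window); channel-specific
    # gains expand to one row per channel.
    gt_rows <- do.call(rbind, lapply(bands, function(bd) {
      do.call(rbind, lapply(seq_len(config$n_trials), function(i) {
        do.call(rbind, lapply(seq_along(intervals), function(w) {
          chans <- if (chan_specific) config$channels else "all"
          g <- vapply(chans, function(ch) {
            lookup_gain(config$amplitude_gain, quadrants[i], bd, w, ch)
          }, numeric(1))
          data.frame(subject = sid, trial = i, type = quadrants[i],
                     band = bd, window = w, channel = chans, gain = g,
                     expected_index = 100 * (1 - g^2),
                     stringsAsFactors = FALSE, row.names = NULL)
        }))
      }))
    }))
    gt[[sid]] <- gt_rows
  }

  names(recordings) <- vapply(recordings, function(r) r$subject_id,
                              character(1))
  list(recordings = recordings,
       events = do.call(rbind, c(events, list(make.row.names = FALSE))),
       behavior = do.call(rbind, c(behavior, list(make.row.names = FALSE))),
       ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE))),
       artifact_log = if (length(art) > 0L)
         do.call(rbind, c(art, list(make.row.names = FALSE)))
       else empty_artifact_log())
}

empty_artifact_log <- function() {
  data.frame(subject = character(), onset_s = numeric(),
             duration_s = numeric(), type = character(),
             stringsAsFactors = FALSE)
}

#' Inject ocular and muscular transients into a recording
#'
#' Artifact onsets follow a Poisson process at `rate` per minute; each
#' event is an ocular transient (a large slow blink-like deflection,
#' strongest at frontopolar sites and decaying towards posterior sites)
#' or a muscular burst (broadband high-frequency noise on a random
#' channel subset) with equal probability. Every injected event is
#' logged with onset, duration and type so that downstream artifact
#' detection can be scored against a known answer.
#'
#' @param recording An [eeg_recording()].
#' @param rate Events per minute; 0 returns the input unchanged.
#' @param seed Optional integer seed.
#' @return List `recording` (modified copy) and `artifact_log`
#'   (subject, onset_s, duration_s, type).
#' @export
inject_artifacts <- function(recording, rate, seed = NULL) {
  stopifnot(rate >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- ncol(recording$data)
  fs <- recording$fs
  duration_min <- n / fs / 60
  if (rate == 0 || duration_min <= 0) {
    return(list(recording = recording, artifact_log = empty_artifact_log()))
  }
  k <- stats::rpois(1, rate * duration_min)
  if (k == 0L) {
    return(list(recording = recording, artifact_log = empty_artifact_log()))
  }
  pos <- montage_1020(recording$channel_labels)
  # Frontal weighting for ocular events: anterior (y > 0) sites loaded,
  # frontopolar strongest, posterior sites untouched.
  w_front <- pmax(0, pos$y)^2
  log <- vector("list", k)
  for (i in seq_len(k)) {
    type <- sample(c("ocular", "muscular"), 1)
    dur <- if (type == "ocular") 0.4 else 0.5
    onset <- stats::runif(1, 0, n / fs - dur)
    a <- round(onset * fs) + 1L
    b <- min(n, a + round(dur * fs) - 1L)
    m <- b - a + 1L
    if (type == "ocular") {
      amp <- stats::runif(1, 200, 350)
      shape <- sin(pi * seq_len(m) / m)^2
      recording$data[, a:b] <- recording$data[, a:b] +
        outer(w_front, amp * shape)
    } else {
      n_ch <- max(1L, round(0.3 * nrow(recording$data)))
      chans <- sample(nrow(recording$data), n_ch)
      envl <- sin(pi * seq_len(m) / m)
      burst <- matrix(stats::rnorm(n_ch * m, 0, 60), nrow = n_ch)
      recording$data[chans, a:b] <- recording$data[chans, a:b] +
        burst * rep(envl, each = n_ch)
    }
    log[[i]] <- data.frame(subject = recording$subject_id, onset_s = onset,
                           duration_s = dur, type = type,
                           stringsAsFactors = FALSE)
  }
  list(recording = recording,
       artifact_log = do.call(rbind, c(log, list(make.row.names = FALSE))))
}
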
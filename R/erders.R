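#' Instantaneous band power via the Hilbert envelope
#'
#' Each epoch channel is band-pass filtered (zero-phase 4th-order
#' Butterworth at the band edges) and converted to instantaneous power as
#' the squared magnitude of the analytic signal. The envelope-power
#' convention is `|analytic|^2`, so a unit-amplitude sine has power 1
#' (not 1/2); every downstream quantity and every oracle in the test
#' suite uses the same convention. A 0.5-s edge guard at each epoch end
#' is recorded and enforced whenever window statistics are taken, since
#' the analytic signal is unreliable near the epoch edges.
#'
#' @param epochs An [epoch_extract()] result (broadband-filtered,
#'   artifact-masked).
#' @param band One-row band definition ([band_definition()]); must lie
#'   inside the broadband passband.
#' @param passband Broadband limits the epochs were filtered to.
#' @param edge_guard_s Edge transient guard, seconds.
#' @param order Butterworth order of the band filter.
#' @return Array trials x channels x samples of instantaneous power
#'   (uV^2) with attribute `edge_guard_s`.
#' @export
band_power <- function(epochs, band, passband = c(0.3, 40),
                       edge_guard_s = 0.5, order = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (band$low < passband[1] || band$high > passband[2])
    stop("parameter error: band ", band$name, " (", band$low, "-",
         band$high, " Hz) is wider than the broadband passband")
  nyq <- epochs$fs / 2
  bf <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  d <- dim(epochs$data)
  pow <- array(0, dim = d, dimnames = dimnames(epochs$data))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- signal::filtfilt(bf, epochs$data[i, j, ])
      pow[i, j, ] <- Mod(analytic_signal(x))^2
    }
  }
  attr(pow, "edge_guard_s") <- edge_guard_s
  pow
}

# Analytic signal by FFT half-spectrum doubling: positive frequencies
# doubled, negative zeroed, DC (and Nyquist for even n) kept.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Group-averaged baseline power
#'
#' The baseline power per channel is the mean of instantaneous band
#' power over the group's epochs and over the baseline-window samples
#' (averaging the baselines across epochs reduces background noise
#' before the index is formed). Computed separately per
#' (subject, performance type, band).
#'
#' @param power Output of [band_power()].
#' @param epochs The matching `eeg_epochs`.
#' @param group Integer/logical index of the group's epochs.
#' @param baseline Baseline window, seconds.
#' @return Named numeric, baseline power per channel (uV^2), or `NULL`
#'   (with a warning) for an empty group.
#' @export
group_baseline <- function(power, epochs, group,
                           baseline = analysis_windows()$baseline) {
  guard <- attr(power, "edge_guard_s") %||% 0
  idx <- window_indices(epochs, baseline, guard)
  sel <- power[group, , idx, drop = FALSE]
  if (dim(sel)[1] == 0L) {
    warning("empty epoch group: baseline skipped, map cell set to missing")
    return(NULL)
  }
  apply(sel, 2, mean)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-epoch ERD/ERS index
#'
#' With `P_int` the mean instantaneous power in an interval and `P_base`
#' the group baseline power, the index is
#' `sign * 100 * (P_int - P_base) / P_base`. Under the default
#' convention (`sign_convention = "erd_positive"`, sign = -1) a power
#' *decrease* yields a positive index (ERD, event-related
#' desynchronization) and a power *increase* a negative index (ERS,
#' synchronization), matching the sign usage of the reported statistics;
#' `"raw_percent_change"` gives the plain percent change instead.
#'
#' @param power Output of [band_power()].
#' @param epochs The matching `eeg_epochs`.
#' @param P_base Baseline power per channel ([group_baseline()]).
#' @param intervals List of interval windows (seconds).
#' @param group Epoch indices to compute indices for.
#' @param sign_convention `"erd_positive"` (default) or
#'   `"raw_percent_change"`.
#' @return Array epochs x channels x intervals of index percentages;
#'   channels with `P_base == 0` give `NA` with a warning.
#' @export
erders_index <- function(power, epochs, P_base,
                         intervals = analysis_windows()$intervals,
                         group = seq_len(dim(power)[1]),
                         sign_convention = c("erd_positive",
                                             "raw_percent_change")) {
  sign_convention <- match.arg(sign_convention)
  sgn <- if (sign_convention == "erd_positive") -1 else 1
  guard <- attr(power, "edge_guard_s") %||% 0
  if (is.logical(group)) group <- which(group)
  n_ch <- dim(power)[2]
  zero_base <- !is.na(P_base) & P_base == 0
  if (any(zero_base)) {
    warning("P_base = 0 for channel(s) ",
            paste(epochs$channel_labels[zero_base], collapse = ", "),
            "; index set to missing")
  }
  out <- array(NA_real_,
               dim = c(length(group), n_ch, length(intervals)),
               dimnames = list(NULL, epochs$channel_labels,
                               names(intervals)))
  for (w in seq_along(intervals)) {
    idx <- window_indices(epochs, intervals[[w]], guard)
    p_int <- apply(power[group, , idx, drop = FALSE], c(1, 2), mean)
    ratio <- sweep(p_int, 2, P_base, "/")
    ratio[, zero_base] <- NA_real_
    out[, , w] <- sgn * 100 * (ratio - 1)
  }
  out
}

#' ERD/ERS maps per subject, performance type and band
#'
#' For every (subject, performance type, band) group of artifact-free
#' epochs: the group baseline is averaged, per-epoch index maps are
#' computed against it, and the single-epoch maps are averaged into one
#' channels x intervals matrix. `average = "power_first"` instead
#' averages interval power across the group's epochs before forming the
#' index (exposed for sensitivity checks; the default, per-epoch order
#' matches the procedure the pipeline models).
#'
#' @param epochs `eeg_epochs` for one subject (artifact mask applied).
#' @param types Character vector assigning a performance type to every
#'   trial row of `epochs$trials`.
#' @param bands Band table ([default_bands()]).
#' @param windows [analysis_windows()].
#' @param sign_convention See [erders_index()].
#' @param edge_guard_s,passband,order Passed to [band_power()].
#' @param average `"epochwise"` (default) or `"power_first"`.
#' @return Object of class `erders_maps`: list with `entries` (keyed
#'   `subject|type|band`, each holding `index` channels x intervals,
#'   `P_base`, `n`), `channel_labels`, `intervals`, `bands`, `subject`.
#' @export
compute_erders <- function(epochs, types, bands = default_bands(),
                           windows = analysis_windows(),
                           sign_convention = "erd_positive",
                           edge_guard_s = 0.5, passband = c(0.3, 40),
                           order = 4, average = c("epochwise",
                                                  "power_first")) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            length(types) == dim(epochs$data)[1])
  average <- match.arg(average)
  subject <- epochs$trials$subject[1]
  good <- !epochs$artifact_bad
  entries <- list()
  for (bi in seq_len(nrow(bands))) {
    band <- bands[bi, ]
    pow <- band_power(epochs, band, passband = passband,
                      edge_guard_s = edge_guard_s, order = order)
    for (ty in performance_types()) {
      group <- which(good & types == ty)
      key <- paste(subject, ty, band$name, sep = "|")
      if (length(group) == 0L) {
        warning("no usable epochs for ", key, "; group skipped")
        next
      }
      P_base <- group_baseline(pow, epochs, group, windows$baseline)
      if (average == "epochwise") {
        idx <- erders_index(pow, epochs, P_base, windows$intervals,
                            group, sign_convention)
        m <- apply(idx, c(2, 3), mean)
      } else {
        guard <- edge_guard_s
        sgn <- if (sign_convention == "erd_positive") -1 else 1
        m <- vapply(windows$intervals, function(iv) {
          s <- window_indices(epochs, iv, guard)
          p_int <- apply(pow[group, , s, drop = FALSE], 2, mean)
          sgn * 100 * (p_int - P_base) / P_base
        }, numeric(length(epochs$channel_labels)))
        dimnames(m) <- list(epochs$channel_labels,
                            names(windows$intervals))
      }
      entries[[key]] <- list(subject = subject, type = ty,
                             band = band$name, index = m,
                             P_base = P_base, n = length(group))
    }
  }
  structure(list(entries = entries,
                 channel_labels = epochs$channel_labels,
                 intervals = names(windows$intervals),
                 bands = bands$name, subject = subject),
            class = "erders_maps")
}

#' Combine per-subject maps and average across subjects
#'
#' `combine_erders()` concatenates `erders_maps` objects from several
#' subjects; `grand_average()` averages the per-subject matrices with
#' equal subject weight per (performance type, band), regardless of how
#' many epochs each subject contributed. Subjects missing a type are
#' omitted from that type's grand mean and counted in `n_subjects`.
#'
#' @param ... `erders_maps` objects.
#' @param maps A combined `erders_maps`.
#' @return `grand_average()` returns a list keyed `type|band` with
#'   `index` (channels x intervals), `n_subjects`, and `subjects` used.
#' @export
combine_erders <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && !inherits(objs[[1]], "erders_maps"))
    objs <- objs[[1]]
  out <- objs[[1]]
  for (o in objs[-1]) {
    stopifnot(identical(o$channel_labels, out$channel_labels))
    out$entries <- c(out$entries, o$entries)
  }
  out$subject <- NULL
  out
}

#' @rdname combine_erders
#' @export
grand_average <- function(maps) {
  stopifnot(inherits(maps, "erders_maps"))
  info <- do.call(rbind, lapply(maps$entries, function(e) {
    data.frame(subject = e$subject, type = e$type, band = e$band,
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (ty in performance_types()) {
    for (bd in maps$bands) {
      keys <- names(maps$entries)[info$type == ty & info$band == bd]
      if (length(keys) == 0L) next
      mats <- lapply(maps$entries[keys], `[[`, "index")
      out[[paste(ty, bd, sep = "|")]] <- list(
        type = ty, band = bd,
        index = Reduce(`+`, mats) / length(mats),
        n_subjects = length(mats),
        subjects = vapply(maps$entries[keys], `[[`, character(1),
                          "subject"))
    }
  }
  out
}

#' Long-format ERD/ERS table
#'
#' Flattens an `erders_maps` object into the long table consumed by the
#' statistics stage and by [write_erders_table()]: one row per (subject,
#' performance type, band, channel, interval).
#'
#' @param maps An `erders_maps`.
#' @return Data frame with columns `subject`, `performance_type`,
#'   `band`, `channel`, `interval`, `erders_pct`, `n_epochs`.
#' @export
erders_long <- function(maps) {
  stopifnot(inherits(maps, "erders_maps"))
  rows <- lapply(maps$entries, function(e) {
    data.frame(subject = e$subject, performance_type = e$type,
               band = e$band,
               channel = rep(rownames(e$index), times = ncol(e$index)),
               interval = rep(seq_len(ncol(e$index)),
                              each = nrow(e$index)),
               erders_pct = as.vector(e$index), n_epochs = e$n,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
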
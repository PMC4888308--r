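#' Frequency bands of the pre-shot analysis
#'
#' Default band edges: theta 4-8 Hz, low alpha 8-10 Hz, high alpha
#' 10-12 Hz. The alpha split at 10 Hz is justified by the near-identical
#' individual alpha frequency across elite shooters (about 9.9-10.1 Hz),
#' which licenses fixed rather than individually adjusted edges.
#'
#' @param name Band name.
#' @param low,high Band edges in Hz.
#' @return `band_definition()` returns a one-row data frame with columns
#'   `name`, `low`, `high`; `default_bands()` returns the three standard
#'   bands stacked.
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high), low > 0, high > low)
  data.frame(name = name, low = low, high = high, stringsAsFactors = FALSE)
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  rbind(band_definition("theta", 4, 8),
        band_definition("low_alpha", 8, 10),
        band_definition("high_alpha", 10, 12))
}

#' Baseline and interval windows of the ERD/ERS analysis
#'
#' The baseline is the second from -5 to -4 s before shot release
#' (earlier periods are contaminated by body and head adjustments and are
#' not allowed); the intervals of interest are the three contiguous 1-s
#' windows covering the final 3 s before the shot.
#'
#' @param baseline Numeric length-2, baseline window in seconds relative
#'   to shot release. Must not start before -5 s.
#' @param intervals List of numeric length-2 windows.
#' @return List with elements `baseline` and `intervals` (named by
#'   "\[lo,hi)" convention strings), class `analysis_windows`.
#' @export
analysis_windows <- function(baseline = c(-5, -4),
                             intervals = list(c(-3, -2), c(-2, -1), c(-1, 0))) {
  stopifnot(length(baseline) == 2L, baseline[1] < baseline[2])
  if (baseline[1] < -5) {
    stop("baseline may not start before -5 s relative to the shot")
  }
  for (iv in intervals) {
    stopifnot(length(iv) == 2L, iv[1] < iv[2])
    if (iv[1] < baseline[2]) {
      if (max(iv[1], baseline[1]) < min(iv[2], baseline[2])) {
        stop("analysis intervals must be disjoint from the baseline")
      }
    }
  }
  names(intervals) <- vapply(intervals, function(iv) {
    sprintf("[%g,%g)", iv[1], iv[2])
  }, character(1))
  structure(list(baseline = baseline, intervals = intervals),
            class = "analysis_windows")
}

#' Performance-type labels of the MAP quadrants
#'
#' Type1 = optimal-automatic, Type2 = optimal-controlled,
#' Type3 = suboptimal-controlled, Type4 = suboptimal-automatic.
#' @return Character vector of the four labels in order.
#' @export
performance_types <- function() c("Type1", "Type2", "Type3", "Type4")
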
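#' Quadrant rule for MAP performance categorization
#'
#' Trials are crossed on two dichotomies: performance level (optimal when
#' `score >= score_threshold`, else suboptimal) and action control
#' (automatic when `control <= control_threshold`, else controlled). The
#' fixed defaults are a score cut of 10.2 (scores from 10.2 up to the
#' maximal 10.9 count as optimal) and a Borg-scale control cut of 4.
#' Boundary closure (`>=` for optimal, `<=` for automatic) follows the
#' more explicit of the two statements the cut-offs come from and is
#' exposed here as configuration.
#'
#' @param score_threshold Score cut-off (scale 0-10.9).
#' @param control_threshold Control cut-off (scale 0-11).
#' @param mode `"fixed"` or `"median_split"`.
#' @param optimal_closed,automatic_closed Whether the threshold value
#'   itself counts as optimal / automatic.
#' @return List of class `quadrant_rule`.
#' @export
quadrant_rule <- function(score_threshold = 10.2, control_threshold = 4,
                          mode = c("fixed", "median_split"),
                          optimal_closed = TRUE, automatic_closed = TRUE) {
  mode <- match.arg(mode)
  if (score_threshold < 0 || score_threshold > 10.9)
    stop("score threshold outside the 0-10.9 scale")
  if (control_threshold < 0 || control_threshold > 11)
    stop("control threshold outside the 0-11 scale")
  structure(list(score_threshold = score_threshold,
                 control_threshold = control_threshold, mode = mode,
                 optimal_closed = optimal_closed,
                 automatic_closed = automatic_closed),
            class = "quadrant_rule")
}

#' Derive categorization thresholds from behaviour
#'
#' `mode = "median_split"` returns the medians of score and control,
#' pooled across subjects by default (one cut-off for all athletes) or
#' per subject with `per_subject = TRUE`; `mode = "fixed"` returns the
#' standard rule (10.2 / 4) regardless of the data.
#'
#' @param behavior Behaviour table (`subject`, `trial`, `score`,
#'   `control`).
#' @param mode `"fixed"` or `"median_split"`.
#' @param per_subject Median-split within each subject; returns a list
#'   of rules keyed by subject.
#' @return A [quadrant_rule()] (or a list of them).
#' @export
derive_thresholds <- function(behavior, mode = c("fixed", "median_split"),
                              per_subject = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(quadrant_rule(mode = "fixed"))
  if (nrow(behavior) < 2L)
    stop("need at least 2 trials for a median split")
  split_one <- function(df) {
    for (v in c("score", "control")) {
      if (length(unique(df[[v]])) == 1L)
        stop("degenerate-split error: all '", v, "' values identical (",
             df[[v]][1], "); a median split cannot separate them")
    }
    quadrant_rule(score_threshold = stats::median(df$score),
                  control_threshold = stats::median(df$control),
                  mode = "median_split")
  }
  if (per_subject) {
    return(lapply(split(behavior, behavior$subject), split_one))
  }
  split_one(behavior)
}

#' Assign each trial to a MAP performance quadrant
#'
#' @param score,control Numeric vectors within their scale bounds.
#' @param rule A [quadrant_rule()].
#' @return Character vector of types (`Type1` optimal-automatic, `Type2`
#'   optimal-controlled, `Type3` suboptimal-controlled, `Type4`
#'   suboptimal-automatic); exactly one per trial.
#' @export
assign_quadrant <- function(score, control, rule = quadrant_rule()) {
  if (any(score < 0 | score > 10.9))
    stop("validation error: score outside [0, 10.9]")
  if (any(control < 0 | control > 11))
    stop("validation error: control outside [0, 11]")
  optimal <- if (rule$optimal_closed) score >= rule$score_threshold
             else score > rule$score_threshold
  automatic <- if (rule$automatic_closed)
    control <= rule$control_threshold
  else control < rule$control_threshold
  ifelse(optimal,
         ifelse(automatic, "Type1", "Type2"),
         ifelse(automatic, "Type4", "Type3"))
}

#' Per-type trial counts
#'
#' @param behavior Behaviour table.
#' @param rule A [quadrant_rule()].
#' @return Named integer vector over the four types; sums to the number
#'   of trials.
#' @export
quadrant_counts <- function(behavior, rule = quadrant_rule()) {
  ty <- assign_quadrant(behavior$score, behavior$control, rule)
  counts <- table(factor(ty, levels = performance_types()))
  stats::setNames(as.integer(counts), performance_types())
}
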
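#' Read and write shot-event tables
#'
#' Events are tab-separated with a header; onsets are stored in seconds
#' (sampling-rate independent) and mapped to sample indices with
#' `round(onset * fs)`. The reader accepts either `onset_s` or `onset`
#' as the onset column name and validates that onsets are strictly
#' increasing within each subject.
#'
#' @param path File path.
#' @param events Data frame with columns `subject`, `trial`, `onset_s`.
#' @return `read_events()` returns the validated data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("onset" %in% names(df) && !"onset_s" %in% names(df)) {
    names(df)[names(df) == "onset"] <- "onset_s"
  }
  need <- c("subject", "trial", "onset_s")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("schema error: events file lacks column(s): ",
         paste(missing, collapse = ", "))
  df$onset_s <- as.numeric(df$onset_s)
  df$trial <- as.integer(df$trial)
  if (anyNA(df$onset_s) || anyNA(df$trial))
    stop("validation error: non-numeric onset or trial values")
  for (s in unique(df$subject)) {
    o <- df$onset_s[df$subject == s]
    if (any(diff(o) <= 0))
      stop("validation error: onsets not strictly increasing for subject ", s)
  }
  df[, need]
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("subject", "trial", "onset_s")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-trial behaviour tables
#'
#' Comma-separated with header `subject,trial,score,control`; scores must
#' lie in \[0, 10.9\] and perceived control in \[0, 11\] (Borg scale), with
#' one row per (subject, trial).
#'
#' @param path File path.
#' @param behavior Data frame with the four required columns.
#' @return `read_behavior()` returns the validated data frame.
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "score", "control")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("schema error: behavior file lacks column(s): ",
         paste(missing, collapse = ", "))
  validate_behavior(df)
  df
}

validate_behavior <- function(df) {
  if (any(df$score < 0 | df$score > 10.9))
    stop("validation error: score outside [0, 10.9]")
  if (any(df$control < 0 | df$control > 11))
    stop("validation error: control outside [0, 11]")
  if (anyDuplicated(df[, c("subject", "trial")]))
    stop("validation error: duplicated (subject, trial) rows")
  invisible(df)
}

#' @rdname read_behavior
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior[, c("subject", "trial", "score", "control")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write long-format ERD/ERS tables
#'
#' Long TSV with columns `subject`, `performance_type`, `band`,
#' `channel`, `interval`, `erders_pct`; values are written with six
#' decimals (a lossless round trip at that precision) and missing cells
#' as `NA`. On read, a table that does not cover all four performance
#' types is flagged incomplete via the `complete` attribute.
#'
#' @param erders Long-format data frame (see [erders_long()]).
#' @param path File path.
#' @return `read_erders_table()` returns the data frame with attribute
#'   `complete`.
#' @export
write_erders_table <- function(erders, path) {
  need <- c("subject", "performance_type", "band", "channel", "interval",
            "erders_pct")
  stopifnot(all(need %in% names(erders)))
  out <- erders[, need]
  out$erders_pct <- ifelse(is.na(out$erders_pct), "NA",
                           sprintf("%.6f", out$erders_pct))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_erders_table
#' @export
read_erders_table <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  need <- c("subject", "performance_type", "band", "channel", "interval",
            "erders_pct")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("schema error: ERD/ERS table lacks column(s): ",
         paste(missing, collapse = ", "))
  df$erders_pct <- as.numeric(df$erders_pct)
  complete <- all(performance_types() %in% df$performance_type)
  if (!complete)
    warning("ERD/ERS table is incomplete: missing performance type(s) ",
            paste(setdiff(performance_types(), df$performance_type),
                  collapse = ", "))
  attr(df, "complete") <- complete
  df
}
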
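#' Two-way within-subject (repeated measures) ANOVA
#'
#' Operates on a complete subjects x A x B table of cell means (here: A
#' = 4 performance types, B = 3 pre-shot intervals, one value per
#' subject and cell). Sums of squares are partitioned into subjects, A,
#' A x S, B, B x S, A x B and A x B x S; each within effect is tested
#' against its own subject-interaction error term
#' (`F_A = MS_A / MS_AxS`, etc.). Sphericity is assessed per effect with
#' Mauchly's test on the orthonormal-contrast covariance;
#' Greenhouse-Geisser and Huynh-Feldt epsilons are reported, and the
#' corrected p-value uses Huynh-Feldt-scaled degrees of freedom
#' according to `correction`: `"mauchly-gated"` (default) corrects only
#' when Mauchly's p < `alpha_sphericity`, `"always"` always corrects,
#' `"never"` never does. Reported degrees of freedom are always the
#' uncorrected integers, with the epsilons alongside.
#'
#' @param cells Numeric array subjects x A x B, no missing cells,
#'   >= 2 subjects.
#' @param correction Sphericity-correction policy.
#' @param alpha_sphericity Mauchly gate level.
#' @return Data frame with one row per effect (`A`, `B`, `A:B`):
#'   `effect`, `df1`, `df2`, `SS`, `MS`, `SS_error`, `MS_error`, `F`,
#'   `p_uncorrected`, `epsilon_GG`, `epsilon_HF`, `mauchly_W`,
#'   `sphericity_p`, `p_corrected`, `eta_p2`; the full partition
#'   (including subjects and `SS_total`) is in attribute `partition`.
#' @export
rm_anova <- function(cells, correction = c("mauchly-gated", "always",
                                           "never"),
                     alpha_sphericity = 0.05) {
  correction <- match.arg(correction)
  stopifnot(is.array(cells), length(dim(cells)) == 3L)
  n <- dim(cells)[1]; a <- dim(cells)[2]; b <- dim(cells)[3]
  if (n < 2L) stop("design error: need at least 2 subjects")
  if (anyNA(cells)) {
    bad <- which(is.na(cells), arr.ind = TRUE)
    stop("design error: missing cell(s): ",
         paste(apply(bad, 1, function(r)
           sprintf("(subject %d, A%d, B%d)", r[1], r[2], r[3])),
           collapse = ", "))
  }
  gm <- mean(cells)
  m_s <- apply(cells, 1, mean)
  m_a <- apply(cells, 2, mean)
  m_b <- apply(cells, 3, mean)
  m_sa <- apply(cells, c(1, 2), mean)
  m_sb <- apply(cells, c(1, 3), mean)
  m_ab <- apply(cells, c(2, 3), mean)

  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + gm)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  ss_total <- sum((cells - gm)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_as - ss_bs - ss_ab

  eff <- data.frame(
    effect = c("A", "B", "A:B"),
    df1 = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
    df2 = c((a - 1L) * (n - 1L), (b - 1L) * (n - 1L),
            (a - 1L) * (b - 1L) * (n - 1L)),
    SS = c(ss_a, ss_b, ss_ab),
    SS_error = c(ss_as, ss_bs, ss_abs),
    stringsAsFactors = FALSE)
  eff$MS <- eff$SS / eff$df1
  eff$MS_error <- eff$SS_error / eff$df2
  eff$F <- ifelse(eff$MS_error > 0, eff$MS / eff$MS_error, NA_real_)
  if (any(eff$MS_error == 0))
    warning("degenerate error term (MS_error = 0); F flagged as NA")
  eff$p_uncorrected <- stats::pf(eff$F, eff$df1, eff$df2,
                                 lower.tail = FALSE)

  sph <- lapply(c("A", "B", "A:B"), function(e) sphericity(cells, e))
  eff$epsilon_GG <- vapply(sph, `[[`, numeric(1), "epsilon_GG")
  eff$epsilon_HF <- vapply(sph, `[[`, numeric(1), "epsilon_HF")
  eff$mauchly_W <- vapply(sph, `[[`, numeric(1), "mauchly_W")
  eff$sphericity_p <- vapply(sph, `[[`, numeric(1), "sphericity_p")

  apply_corr <- switch(correction,
    "mauchly-gated" = !is.na(eff$sphericity_p) &
      eff$sphericity_p < alpha_sphericity,
    "always" = rep(TRUE, 3L),
    "never" = rep(FALSE, 3L))
  eps <- pmin(eff$epsilon_HF, 1)
  eff$p_corrected <- ifelse(apply_corr,
                            stats::pf(eff$F, eff$df1 * eps,
                                      eff$df2 * eps, lower.tail = FALSE),
                            eff$p_uncorrected)
  eff$eta_p2 <- ifelse(is.na(eff$F), NA_real_,
                       partial_eta_squared(eff$F, eff$df1, eff$df2))
  attr(eff, "partition") <- c(subjects = ss_s, A = ss_a, `A:S` = ss_as,
                              B = ss_b, `B:S` = ss_bs, `A:B` = ss_ab,
                              `A:B:S` = ss_abs, total = ss_total)
  attr(eff, "dims") <- c(n = n, a = a, b = b)
  eff
}

# Orthonormal contrast matrix ((k-1) x k) orthogonal to the constant.
orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  t(apply(H, 2, function(col) col / sqrt(sum(col^2))))
}

#' Sphericity diagnostics for one within-subject effect
#'
#' Per-subject effect scores (level means for a main effect; cell values
#' under the Kronecker product of both factors' contrasts for the
#' interaction) are projected on orthonormal contrasts; with `M` the
#' contrast covariance and `p` the effect's numerator degrees of
#' freedom, Greenhouse-Geisser epsilon is `tr(M)^2 / (p * tr(M^2))` and
#' Huynh-Feldt epsilon is `min(1, (n p eGG - 2) / (p (n - 1 - p eGG)))`.
#' Mauchly's W and its chi-square p-value gate the correction. Effects
#' with a single contrast dimension are trivially spherical
#' (epsilon = 1). When subjects are too few for a full-rank contrast
#' covariance (`n - 1 < p`) the epsilons still follow the trace formulas
#' (which need no inversion) but Mauchly's determinant is degenerate;
#' the test is then reported as `NA` with a warning.
#'
#' @param cells Subjects x A x B array.
#' @param effect `"A"`, `"B"` or `"A:B"`.
#' @return List `mauchly_W`, `sphericity_p`, `epsilon_GG`, `epsilon_HF`.
#' @export
sphericity <- function(cells, effect = c("A", "B", "A:B")) {
  effect <- match.arg(effect)
  n <- dim(cells)[1]; a <- dim(cells)[2]; b <- dim(cells)[3]
  if (effect == "A") {
    Z <- apply(cells, c(1, 2), mean)
    C <- orthonormal_contrasts(a)
  } else if (effect == "B") {
    Z <- apply(cells, c(1, 3), mean)
    C <- orthonormal_contrasts(b)
  } else {
    Z <- matrix(aperm(cells, c(1, 3, 2)), nrow = n)  # B fastest
    C <- kronecker(orthonormal_contrasts(a), orthonormal_contrasts(b))
  }
  p <- nrow(C)
  if (p == 1L) {
    return(list(mauchly_W = 1, sphericity_p = NA_real_,
                epsilon_GG = 1, epsilon_HF = 1))
  }
  M <- C %*% stats::cov(Z) %*% t(C)
  trM <- sum(diag(M))
  trM2 <- sum(M * M)
  gg <- if (trM2 > 0) trM^2 / (p * trM2) else NA_real_
  hf <- if (is.na(gg)) NA_real_ else
    min(1, (n * p * gg - 2) / (p * (n - 1 - p * gg)))
  if (n - 1 < p) {
    warning("contrast covariance is singular (n - 1 < ", p, "); ",
            "epsilons use the trace formulas, Mauchly's test is NA")
    return(list(mauchly_W = NA_real_, sphericity_p = NA_real_,
                epsilon_GG = gg, epsilon_HF = hf))
  }
  W <- det(M) / (trM / p)^p
  if (!is.finite(W) || W <= 0) {
    return(list(mauchly_W = W, sphericity_p = NA_real_,
                epsilon_GG = gg, epsilon_HF = hf))
  }
  f <- (n - 1) - (2 * p^2 + p + 2) / (6 * p)
  chi2 <- -f * log(W)
  df <- p * (p + 1) / 2 - 1
  list(mauchly_W = W,
       sphericity_p = stats::pchisq(chi2, df, lower.tail = FALSE),
       epsilon_GG = gg, epsilon_HF = hf)
}

#' Partial eta squared from F and degrees of freedom
#'
#' `eta_p2 = F * df1 / (F * df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)` for the corresponding effect.
#'
#' @param F,df1,df2 F statistic and its (uncorrected) degrees of
#'   freedom.
#' @return Effect size in \[0, 1\].
#' @export
partial_eta_squared <- function(F, df1, df2) {
  stopifnot(all(F >= 0, na.rm = TRUE), all(df1 > 0), all(df2 > 0))
  F * df1 / (F * df1 + df2)
}

#' Fisher LSD pairwise comparisons for a within-subject main effect
#'
#' Unadjusted pairwise t-tests on the marginal level means, using the
#' effect's own ANOVA error term:
#' `t_ij = (m_i - m_j) / sqrt(2 MS_error / n_eff)` with `n_eff` the
#' number of observations behind each marginal mean (subjects x levels
#' of the other factor) and the error term's degrees of freedom. No
#' multiplicity correction (that is the LSD); classical protection is to
#' run it only after a significant omnibus effect.
#'
#' @param cells Subjects x A x B array.
#' @param effect `"A"` or `"B"`.
#' @param anova Optional precomputed [rm_anova()] result for `cells`.
#' @param level_names Optional labels for the effect's levels.
#' @return Data frame of pairs: `level_i`, `level_j`, `mean_i`,
#'   `mean_j`, `diff`, `t`, `df`, `p`.
#' @export
fisher_lsd <- function(cells, effect = c("A", "B"), anova = NULL,
                       level_names = NULL) {
  effect <- match.arg(effect)
  if (is.null(anova)) anova <- rm_anova(cells)
  row <- anova[anova$effect == effect, ]
  if (row$MS_error == 0 || is.na(row$F))
    stop("degenerate error: MS_error = 0 for effect ", effect)
  n <- dim(cells)[1]
  means <- if (effect == "A") apply(cells, 2, mean)
           else apply(cells, 3, mean)
  n_eff <- n * (if (effect == "A") dim(cells)[3] else dim(cells)[2])
  k <- length(means)
  if (is.null(level_names)) level_names <- paste0(effect, seq_len(k))
  pairs <- utils::combn(k, 2)
  se <- sqrt(2 * row$MS_error / n_eff)
  out <- data.frame(
    level_i = level_names[pairs[1, ]], level_j = level_names[pairs[2, ]],
    mean_i = means[pairs[1, ]], mean_j = means[pairs[2, ]],
    stringsAsFactors = FALSE, row.names = NULL)
  out$diff <- out$mean_i - out$mean_j
  out$t <- out$diff / se
  out$df <- row$df2
  out$p <- 2 * stats::pt(-abs(out$t), row$df2)
  out
}

#' Electrode-wise ANOVA battery over the ERD/ERS table
#'
#' One 4 x 3 (performance type x interval) repeated-measures ANOVA per
#' (band, electrode), on per-subject cell-mean indices. Electrodes with
#' incomplete subject x type x interval crossings are skipped and
#' logged. The `significant` summary mirrors the layout of the per-band
#' result tables (effect, electrode, uncorrected dfs, F, corrected p,
#' partial eta squared), filtered at `alpha`. No correction is applied
#' across the electrode x band family by default; `adjust = "BH"`
#' applies Benjamini-Hochberg within each effect family instead.
#'
#' @param erders Long table ([erders_long()] or [read_erders_table()]).
#' @param correction,alpha_sphericity Passed to [rm_anova()].
#' @param alpha Significance filter for the summary.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param posthoc Run [fisher_lsd()] on the performance effect where the
#'   omnibus test is significant.
#' @return List: `results` (all effects, all electrodes), `significant`,
#'   `posthoc` (named by `band|electrode`), `skipped`, `n_subjects`.
#' @export
run_stats_battery <- function(erders, correction = "mauchly-gated",
                              alpha_sphericity = 0.05, alpha = 0.05,
                              adjust = c("none", "BH"), posthoc = TRUE) {
  adjust <- match.arg(adjust)
  need <- c("subject", "performance_type", "band", "channel", "interval",
            "erders_pct")
  stopifnot(all(need %in% names(erders)))
  subjects <- sort(unique(erders$subject))
  types <- performance_types()
  results <- list(); skipped <- character(); ph <- list()
  effect_label <- c(A = "Performance", B = "Time",
                    `A:B` = "Performance x Time")
  for (bd in unique(erders$band)) {
    for (ch in unique(erders$channel)) {
      sub <- erders[erders$band == bd & erders$channel == ch, ]
      ivs <- sort(unique(sub$interval))
      cells <- array(NA_real_, dim = c(length(subjects), length(types),
                                       length(ivs)))
      for (si in seq_along(subjects)) for (ti in seq_along(types))
        for (wi in seq_along(ivs)) {
          v <- sub$erders_pct[sub$subject == subjects[si] &
                                sub$performance_type == types[ti] &
                                sub$interval == ivs[wi]]
          v <- v[!is.na(v)]
          if (length(v) > 0L) cells[si, ti, wi] <- mean(v)
        }
      if (anyNA(cells)) {
        skipped <- c(skipped, paste(bd, ch, sep = "|"))
        next
      }
      an <- rm_anova(cells, correction = correction,
                     alpha_sphericity = alpha_sphericity)
      an$band <- bd
      an$electrode <- ch
      an$variable <- effect_label[an$effect]
      results[[paste(bd, ch, sep = "|")]] <- an
      if (posthoc) {
        perf <- an[an$effect == "A", ]
        if (!is.na(perf$p_corrected) && perf$p_corrected < alpha) {
          ph[[paste(bd, ch, sep = "|")]] <-
            fisher_lsd(cells, "A", anova = an, level_names = types)
        }
      }
    }
  }
  if (length(results) == 0L) stop("pipeline error: no complete electrode")
  res <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  if (adjust == "BH") {
    for (e in unique(res$effect)) {
      i <- res$effect == e
      res$p_corrected[i] <- stats::p.adjust(res$p_corrected[i],
                                            method = "BH")
    }
  }
  sig <- res[!is.na(res$p_corrected) & res$p_corrected < alpha,
             c("variable", "electrode", "band", "df1", "df2", "F",
               "p_corrected", "eta_p2")]
  sig$dfs <- paste(sig$df1, sig$df2, sep = ",")
  list(results = res, significant = sig, posthoc = ph,
       skipped = skipped, n_subjects = length(subjects))
}
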
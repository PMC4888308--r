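# Independent oracles and fixture builders shared across tests.
# None of these call the implementation paths they are used to check.

# Periodogram band power (uV^2) of a vector, mean over [low, high] Hz.
# Independent of the Hilbert-envelope path: direct FFT power summation
# scaled so a unit-amplitude sine inside the band gives 1 under the
# |analytic|^2 convention (sine power A^2/2, envelope power A^2).
oracle_band_power <- function(x, fs, low, high) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= low & f <= high & f <= fs / 2
  # one-sided power x2; envelope convention doubles once more
  2 * 2 * sum(Mod(X[sel])^2) / n^2
}

# Welch-style band power: average of oracle_band_power over 1-s segments.
oracle_welch_band_power <- function(x, fs, low, high, seg_s = 1) {
  seg <- round(seg_s * fs)
  n_seg <- floor(length(x) / seg)
  mean(vapply(seq_len(n_seg), function(i) {
    oracle_band_power(x[((i - 1) * seg + 1):(i * seg)], fs, low, high)
  }, numeric(1)))
}

# Brute-force projection-matrix partition of the two-way within-subject
# ANOVA: y indexed (subject, A, B); each SS is ||P y||^2 for the
# idempotent Kronecker projection onto that term's subspace.
oracle_ss_projection <- function(cells) {
  n <- dim(cells)[1]; a <- dim(cells)[2]; b <- dim(cells)[3]
  J <- function(k) matrix(1 / k, k, k)
  K <- function(k) diag(k) - J(k)
  y <- as.vector(aperm(cells, c(3, 2, 1)))  # B fastest, subject slowest
  P <- function(Ms, Ma, Mb) kronecker(Ms, kronecker(Ma, Mb))
  ss <- function(M) sum((M %*% y)^2)
  c(subjects = ss(P(K(n), J(a), J(b))),
    A = ss(P(J(n), K(a), J(b))),
    `A:S` = ss(P(K(n), K(a), J(b))),
    B = ss(P(J(n), J(a), K(b))),
    `B:S` = ss(P(K(n), J(a), K(b))),
    `A:B` = ss(P(J(n), K(a), K(b))),
    `A:B:S` = ss(P(K(n), K(a), K(b))),
    total = ss(P(diag(n), diag(a), diag(b)) -
                 P(J(n), J(a), J(b))))
}

# aov() oracle for within-subject F and p values.
oracle_aov <- function(cells) {
  n <- dim(cells)[1]; a <- dim(cells)[2]; b <- dim(cells)[3]
  df <- expand.grid(B = factor(seq_len(b)), A = factor(seq_len(a)),
                    S = factor(seq_len(n)))
  df$y <- as.vector(aperm(cells, c(3, 2, 1)))
  fit <- stats::aov(y ~ A * B + Error(S / (A * B)), data = df)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)[1]
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  rbind(A = grab("Error: S:A", "A"), B = grab("Error: S:B", "B"),
        `A:B` = grab("Error: S:A:B", "A:B"))
}

# car::Anova(mlm) oracle for GG epsilon and Mauchly's test of a
# one-group repeated factor with k levels (Z: subjects x levels).
oracle_car_sphericity <- function(Z) {
  k <- ncol(Z)
  colnames(Z) <- paste0("L", seq_len(k))
  fit <- stats::lm(Z ~ 1)
  idata <- data.frame(lev = factor(paste0("L", seq_len(k))))
  an <- car::Anova(fit, idata = idata, idesign = ~lev, type = 3)
  s <- summary(an, multivariate = FALSE)
  list(gg = unname(s$pval.adjustments["lev", "GG eps"]),
       mauchly_W = unname(s$sphericity.tests["lev", "Test statistic"]),
       mauchly_p = unname(s$sphericity.tests["lev", "p-value"]))
}

# Small clean session used by several signal tests.
tiny_config <- function(n_subjects = 1, n_trials = 10, fs = 256,
                        channels = c("Fpz", "Fz", "Cz", "Oz"),
                        inter_shot_mean = 14, inter_shot_jitter = 1,
                        artifact_rate = 0, seed = 11L, ...) {
  simulation_config(n_subjects = n_subjects, n_trials = n_trials,
                    fs = fs, channels = channels,
                    inter_shot_mean = inter_shot_mean,
                    inter_shot_jitter = inter_shot_jitter,
                    artifact_rate = artifact_rate, seed = seed, ...)
}

# Epochs from a deterministic signal function f(t_seconds) -> value,
# replicated over channels; n_trials events, fs, no filtering.
epochs_from_signal <- function(f, n_trials = 2, fs = 256,
                               channels = c("Cz", "Pz"),
                               spacing = 14) {
  onsets <- 8 + spacing * (seq_len(n_trials) - 1)
  dur <- max(onsets) + 6
  t <- seq_len(round(dur * fs)) / fs
  x <- f(t)
  data <- matrix(rep(x, each = length(channels)),
                 nrow = length(channels))
  rec <- eeg_recording(data, fs, channels, subject_id = "S01")
  ev <- data.frame(subject = "S01", trial = seq_len(n_trials),
                   onset_s = onsets)
  epoch_extract(rec, ev)
}

uniform_mix <- function() {
  stats::setNames(rep(0.25, 4), performance_types())
}
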
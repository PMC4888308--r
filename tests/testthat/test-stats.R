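random_cells <- function(n, a, b) {
  array(rnorm(n * a * b, 0, 5), dim = c(n, a, b))
}

test_that("sums of squares match the projection-matrix oracle", {
  set.seed(51)
  shapes <- rbind(c(3, 2, 2), c(4, 3, 2), c(6, 4, 3), c(10, 4, 3),
                  c(5, 2, 4))
  for (r in seq_len(25)) {
    sh <- shapes[(r - 1) %% nrow(shapes) + 1, ]
    cells <- random_cells(sh[1], sh[2], sh[3])
    an <- suppressWarnings(rm_anova(cells))
    oracle <- oracle_ss_projection(cells)
    part <- attr(an, "partition")
    for (term in names(oracle)) {
      expect_equal(part[[term]], oracle[[term]],
                   tolerance = 1e-10 * max(1, oracle[["total"]]))
    }
    expect_equal(part[["total"]],
                 sum(part[setdiff(names(part), "total")]),
                 tolerance = 1e-8 * part[["total"]])
  }
})

test_that("F and p agree with aov() error strata", {
  set.seed(52)
  for (r in 1:5) {
    cells <- random_cells(6, 3, 3)
    an <- rm_anova(cells)
    oa <- oracle_aov(cells)
    for (e in c("A", "B", "A:B")) {
      expect_equal(an$F[an$effect == e], unname(oa[e, "F"]),
                   tolerance = 1e-8)
      expect_equal(an$p_uncorrected[an$effect == e], unname(oa[e, "p"]),
                   tolerance = 1e-8)
    }
  }
})

test_that("the 4x3 design for 10 subjects prints dfs (3,27) (2,18) (6,54)", {
  set.seed(53)
  an <- rm_anova(random_cells(10, 4, 3))
  expect_equal(an$df1, c(3L, 2L, 6L))
  expect_equal(an$df2, c(27L, 18L, 54L))
})

test_that("degenerate designs are rejected or flagged", {
  expect_error(rm_anova(random_cells(1, 4, 3)), "2 subjects")
  cells <- random_cells(4, 4, 3)
  cells[2, 3, 1] <- NA
  expect_error(rm_anova(cells), "subject 2, A3, B1")
  # zero between-level variation: F = 0 on a clean error term
  set.seed(54)
  flatA <- array(0, dim = c(5, 3, 2))
  for (s in 1:5) for (b in 1:2) flatA[s, , b] <- rnorm(1)
  anA <- suppressWarnings(rm_anova(flatA))
  expect_true(anA$F[anA$effect == "A"] == 0 ||
                is.na(anA$F[anA$effect == "A"]))
  # constant table: error MS = 0 -> flagged NA, with warning
  const <- array(1, dim = c(3, 2, 2))
  expect_warning(anc <- rm_anova(const), "degenerate")
  expect_true(all(is.na(anc$F)))
})

test_that("epsilons and Mauchly agree with car::Anova on random data", {
  skip_if_not_installed("car")
  set.seed(55)
  for (r in 1:5) {
    Z <- matrix(rnorm(10 * 3), 10, 3) %*% matrix(rnorm(9), 3, 3)
    cells <- array(0, dim = c(10, 2, 3))
    cells[, 1, ] <- Z
    cells[, 2, ] <- Z  # factor B carries Z's covariance; A is flat
    sp <- sphericity(cells, "B")
    oc <- oracle_car_sphericity(Z)
    expect_equal(sp$epsilon_GG, oc$gg, tolerance = 1e-8)
    expect_equal(sp$mauchly_W, oc$mauchly_W, tolerance = 1e-8)
    expect_equal(sp$sphericity_p, oc$mauchly_p, tolerance = 1e-6)
    # direct-formula identity on the contrast covariance
    C <- preshot:::orthonormal_contrasts(3)
    M <- C %*% stats::cov(Z) %*% t(C)
    expect_equal(sp$epsilon_GG,
                 sum(diag(M))^2 / (2 * sum(M * M)), tolerance = 1e-10)
    # spec formula for Huynh-Feldt from the GG value
    n <- 10; p <- 2
    expect_equal(sp$epsilon_HF,
                 min(1, (n * p * oc$gg - 2) / (p * (n - 1 - p * oc$gg))),
                 tolerance = 1e-8)
  }
})

test_that("two-level effects are trivially spherical; few subjects warn", {
  set.seed(56)
  cells <- random_cells(6, 2, 3)
  sp <- sphericity(cells, "A")
  expect_equal(sp$epsilon_GG, 1)
  expect_equal(sp$epsilon_HF, 1)
  # n - 1 < p: singular contrast covariance
  small <- random_cells(3, 4, 3)
  expect_warning(sp2 <- sphericity(small, "A:B"), "singular")
  expect_true(is.na(sp2$sphericity_p))
  expect_true(sp2$epsilon_GG >= 1 / 6 - 1e-12)
  # epsilon bounds 1/df1 <= eps <= 1 across random draws
  for (r in 1:10) {
    sp3 <- sphericity(random_cells(10, 4, 3), "A")
    expect_gte(sp3$epsilon_GG, 1 / 3 - 1e-12)
    expect_lte(sp3$epsilon_GG, 1 + 1e-12)
  }
})

test_that("correction inflates p in the rejection-relevant region", {
  # df-scaling by eps < 1 raises the tail p for F well above 1 (the
  # region where the correction matters); near F ~ 1 the relation can
  # invert, which is a property of the F distribution, not a bug.
  set.seed(57)
  checked <- 0
  for (r in 1:40) {
    cells <- random_cells(8, 4, 3)
    an <- rm_anova(cells, correction = "always")
    sel <- an$epsilon_HF < 1 & an$F >= 1.5
    checked <- checked + sum(sel)
    expect_true(all(an$p_corrected[sel] >= an$p_uncorrected[sel]))
  }
  expect_gt(checked, 10)
})

test_that("partial eta squared follows F df1 / (F df1 + df2)", {
  expect_equal(round(partial_eta_squared(5.338, 3, 27), 3), 0.372)
  expect_equal(round(partial_eta_squared(8.858, 2, 18), 3), 0.496)
  expect_equal(partial_eta_squared(0, 3, 27), 0)
  # identity with the SS-based value for a fitted table
  set.seed(58)
  cells <- random_cells(6, 4, 3)
  an <- rm_anova(cells)
  expect_equal(an$eta_p2, an$SS / (an$SS + an$SS_error),
               tolerance = 1e-12)
})

test_that("Fisher LSD: t^2 equals F for two levels; flat means give p=1", {
  set.seed(59)
  cells <- random_cells(7, 2, 3)
  an <- rm_anova(cells)
  lsd <- fisher_lsd(cells, "A", anova = an)
  expect_equal(lsd$t^2, an$F[an$effect == "A"], tolerance = 1e-8)
  expect_equal(lsd$df, an$df2[an$effect == "A"])

  # identical level means but real subject-level noise in the error term
  flat <- random_cells(5, 3, 2)
  for (a in 1:3) flat[, a, ] <- flat[, a, ] - mean(flat[, a, ])
  lsd2 <- fisher_lsd(flat, "A")
  expect_equal(lsd2$t, rep(0, 3), tolerance = 1e-12)
  expect_equal(lsd2$p, rep(1, 3), tolerance = 1e-12)

  const <- array(1, dim = c(3, 2, 2))
  expect_error(suppressWarnings(fisher_lsd(const, "A")), "degenerate")
})

test_that("the battery runs one ANOVA per electrode and band", {
  set.seed(60)
  grid <- expand.grid(subject = sprintf("S%02d", 1:4),
                      performance_type = performance_types(),
                      band = c("theta", "low_alpha", "high_alpha"),
                      channel = waveguard32_labels(), interval = 1:3,
                      stringsAsFactors = FALSE)
  grid$erders_pct <- rnorm(nrow(grid), 0, 10)
  out <- run_stats_battery(grid, posthoc = FALSE)
  expect_equal(nrow(out$results), 96L * 3L)  # 3 bands x 32 electrodes
  expect_equal(length(out$skipped), 0L)
  expect_equal(out$n_subjects, 4L)

  # an electrode with a missing cell is skipped and logged
  drop <- !(grid$channel == "Cz" & grid$band == "theta" &
              grid$subject == "S01" & grid$performance_type == "Type1")
  out2 <- run_stats_battery(grid[drop, ], posthoc = FALSE)
  expect_true("theta|Cz" %in% out2$skipped)
  expect_equal(nrow(out2$results), (96L - 1L) * 3L)
})

test_that("a strong single-electrode effect is detected with high power", {
  set.seed(61)
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    cells <- null_index_table(n_subjects = 10, n_trials_per_cell = 20,
                              sd = 15)
    cells[, 3, ] <- cells[, 3, ] + 12  # Type-3 ERD shift at one electrode
    an <- rm_anova(cells)
    hits <- hits + (an$p_corrected[an$effect == "A"] < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})
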
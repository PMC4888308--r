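test_that("identical (config, seed) pairs reproduce identical sessions", {
  cfg <- tiny_config(seed = 3L)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recordings[[1]]$data, s2$recordings[[1]]$data)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$behavior, s2$behavior)
  s3 <- simulate_session(cfg, seed = 4L)
  expect_false(identical(s1$recordings[[1]]$data,
                         s3$recordings[[1]]$data))
})

test_that("ground truth encodes 100*(1 - g^2) with gain 1 giving 0", {
  flat <- default_gain_table()
  flat$gain <- 1
  s <- simulate_session(tiny_config(amplitude_gain = flat))
  expect_true(all(s$ground_truth$expected_index == 0))

  g <- data.frame(type = "Type2", band = "low_alpha", window = "3",
                  channel = "all", gain = 0.7)
  s2 <- simulate_session(tiny_config(amplitude_gain = g))
  gt <- s2$ground_truth
  cell <- gt[gt$type == "Type2" & gt$band == "low_alpha" &
               gt$window == 3, ]
  expect_equal(unique(cell$expected_index), 100 * (1 - 0.49),
               tolerance = 1e-12)
  rest <- gt[!(gt$type == "Type2" & gt$band == "low_alpha" &
                 gt$window == 3), ]
  expect_true(all(rest$expected_index == 0))
})

test_that("session geometry leaves a full epoch around every shot", {
  cfg <- tiny_config(seed = 9L)
  s <- simulate_session(cfg)
  n_s <- ncol(s$recordings[[1]]$data) / cfg$fs
  expect_true(all(s$events$onset_s >= 6))
  expect_true(all(s$events$onset_s + 4 <= n_s))
  expect_equal(nrow(s$events), cfg$n_trials)
})

test_that("configuration errors are caught before any signal is made", {
  expect_error(tiny_config(inter_shot_mean = 8), "inter-shot")
  bad_gain <- default_gain_table()
  bad_gain$gain[1] <- 0
  expect_error(tiny_config(amplitude_gain = bad_gain), "gains")
  expect_error(tiny_config(quadrant_mix = c(Type1 = 0.5, Type2 = 0.5,
                                            Type3 = 0.2, Type4 = 0.2)),
               "sum to 1")
  expect_error(tiny_config(channels = c("Cz", "NOPE")), "NOPE")
  expect_error(tiny_config(fs = 20), "fs")
})

test_that("modulated/baseline Welch power ratio calibrates to g^2", {
  # >= 50 trials, one modulated band, oracle = periodogram power ratio
  # between the last pre-shot second and the baseline second.
  for (g in c(0.7, 1.25)) {
    tab <- data.frame(type = performance_types(), band = "low_alpha",
                      window = "all", channel = "all", gain = g)
    cfg <- simulation_config(n_subjects = 1, n_trials = 52, fs = 256,
                             channels = c("Cz", "Pz"),
                             inter_shot_mean = 14, inter_shot_jitter = 1,
                             amplitude_gain = tab, artifact_rate = 0,
                             noise_sd = 0.5, quadrant_mix = uniform_mix(),
                             seed = 21L)
    s <- simulate_session(cfg)
    x <- s$recordings[[1]]$data[1, ]
    fs <- cfg$fs
    ratios <- vapply(s$events$onset_s, function(on) {
      win <- x[round((on - 1) * fs):(round(on * fs) - 1)]
      base <- x[round((on - 5) * fs):(round((on - 4) * fs) - 1)]
      oracle_band_power(win, fs, 8, 10) /
        oracle_band_power(base, fs, 8, 10)
    }, numeric(1))
    expect_equal(mean(ratios), g^2, tolerance = 0.10 * g^2)
  }
})

test_that("behaviour distributions follow the configured quadrants", {
  cfg <- tiny_config()
  set.seed(5)
  n <- 4000
  for (ty in performance_types()) {
    beh <- simulate_behavior(cfg, rep(ty, n), seed = NULL)
    p <- default_behavior_params()[[ty]]
    expect_true(all(beh$score >= 0 & beh$score <= 10.9))
    expect_true(all(beh$control >= 0 & beh$control <= 11))
    # scores: region-consistent with the table means
    expect_equal(mean(beh$score), p$score_mean, tolerance = 0.05)
    if (ty %in% c("Type2", "Type3")) {
      expect_equal(mean(beh$control), p$control_mean, tolerance = 0.05)
    } else {
      # automatic quadrants: truncated below the control cut-off
      expect_true(all(beh$control <= 4))
    }
    # categorization recovers the generating quadrant exactly
    expect_true(all(assign_quadrant(beh$score, beh$control) == ty))
  }
})

test_that("zero-variance behaviour degenerates to the exact means", {
  params <- default_behavior_params()
  for (ty in names(params)) params[[ty]][c("score_sd", "control_sd")] <- 0
  cfg <- tiny_config(behavior_params = params)
  beh <- simulate_behavior(cfg, c("Type2", "Type2", "Type3"), seed = 1)
  expect_equal(beh$score, c(10.45, 10.45, 9.90))
  expect_equal(beh$control, c(6.47, 6.47, 6.44))
  expect_error(simulate_behavior(cfg, character(0)), "empty")
})

test_that("quadrant mixture converges to quadrant_mix", {
  cfg <- tiny_config()
  n <- 2000
  q <- draw_quadrants(cfg, n, seed = 8L)
  counts <- table(factor(q, levels = performance_types()))
  for (ty in performance_types()) {
    p <- cfg$quadrant_mix[[ty]]
    ci <- stats::binom.test(counts[[ty]], n, p)$conf.int
    expect_true(p >= ci[1] && p <= ci[2])
  }
})

test_that("artifact injection is logged, frontal-weighted, Poisson-rated", {
  cfg <- tiny_config(seed = 2L)
  s <- simulate_session(cfg)
  rec <- s$recordings[[1]]

  out0 <- inject_artifacts(rec, rate = 0, seed = 1)
  expect_identical(out0$recording$data, rec$data)
  expect_equal(nrow(out0$artifact_log), 0L)

  # rate x duration sets the expected count (10-min zero recording)
  zero <- eeg_recording(matrix(0, 4, 64 * 600), 64,
                        c("Fp1", "Fp2", "Cz", "Oz"))
  counts <- vapply(1:30, function(i) {
    nrow(inject_artifacts(zero, rate = 2, seed = i)$artifact_log)
  }, numeric(1))
  expect_equal(mean(counts), 20, tolerance = 0.15)

  one <- inject_artifacts(zero, rate = 2, seed = 7)
  log <- one$artifact_log
  expect_true(all(c("onset_s", "duration_s", "type") %in% names(log)))
  expect_true(all(log$type %in% c("ocular", "muscular")))
  oc <- log[log$type == "ocular", ][1, ]
  if (!is.na(oc$onset_s)) {
    idx <- round(oc$onset_s * 64):(round((oc$onset_s + oc$duration_s) * 64))
    # frontopolar deflection large, occipital untouched
    expect_gt(max(abs(one$recording$data["Fp1", idx])), 100)
    expect_lt(max(abs(one$recording$data["Oz", idx])), 1e-9)
  }
})
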
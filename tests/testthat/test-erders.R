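# Fabricate a minimal eeg_epochs shell plus a power array with known
# window values, for direct index-formula checks.
fake_power_epochs <- function(base_val, interval_vals, n_epochs = 1,
                              n_ch = 2, fs = 64) {
  ep <- structure(list(fs = fs, window = c(-6, 4),
                       t0 = 1L + round(6 * fs),
                       channel_labels = paste0("ch", seq_len(n_ch)),
                       artifact_bad = rep(FALSE, n_epochs)),
                  class = "eeg_epochs")
  pow <- array(base_val, dim = c(n_epochs, n_ch, round(10 * fs)))
  wins <- analysis_windows()$intervals
  for (w in seq_along(wins)) {
    idx <- (ep$t0 + round(wins[[w]][1] * fs)):
      (ep$t0 + round(wins[[w]][2] * fs) - 1)
    pow[, , idx] <- interval_vals[w]
  }
  attr(pow, "edge_guard_s") <- 0.5
  list(ep = ep, pow = pow)
}

test_that("envelope power of a unit sine is A^2 under |analytic|^2", {
  fs <- 256
  ep <- epochs_from_signal(function(t) sin(2 * pi * 10 * t),
                           n_trials = 1, fs = fs,
                           channels = c("Cz", "Pz"))
  pow <- band_power(ep, band_definition("high_alpha_test", 8, 12))
  inner <- (ep$t0 - 5 * fs):(ep$t0 - fs)  # well inside the epoch
  expect_equal(mean(pow[1, 1, inner]), 1.0, tolerance = 0.02)
  # amplitude A scales power as A^2
  ep$data <- ep$data * 3
  pow3 <- band_power(ep, band_definition("high_alpha_test", 8, 12))
  expect_equal(mean(pow3[1, 1, inner]), 9.0, tolerance = 0.02 * 9)
  # zero signal -> zero power
  ep$data[] <- 0
  expect_equal(max(band_power(ep, default_bands()[1, ])), 0)
  expect_error(band_power(ep, band_definition("too_wide", 0.1, 45)),
               "passband")
})

test_that("disjoint band powers add up to the union-band power", {
  fs <- 256
  set.seed(13)
  noise <- rnorm(40 * fs, 0, 5)
  ep <- epochs_from_signal(function(t) noise[seq_along(t)], n_trials = 1,
                           fs = fs, channels = "Cz", spacing = 30)
  inner <- (ep$t0 - 5 * fs):(ep$t0 - fs)
  p_bands <- vapply(seq_len(nrow(default_bands())), function(i) {
    mean(band_power(ep, default_bands()[i, ])[1, 1, inner])
  }, numeric(1))
  p_union <- mean(band_power(ep, band_definition("union", 4, 12))[1, 1,
                                                                  inner])
  expect_equal(sum(p_bands), p_union, tolerance = 0.10 * p_union)
})

test_that("baseline pooling averages epochs and window samples", {
  f <- fake_power_epochs(2, c(2, 2, 2), n_epochs = 2)
  f$pow[2, , ] <- f$pow[2, , ] * 3     # baselines p and 3p
  pb <- group_baseline(f$pow, f$ep, 1:2)
  expect_equal(unname(pb), c(4, 4))    # 2p with p = 2
  pb1 <- group_baseline(f$pow, f$ep, 1)
  expect_equal(unname(pb1), c(2, 2))
  expect_warning(out <- group_baseline(f$pow, f$ep, integer(0)), "empty")
  expect_null(out)
})

test_that("index formula gives 0 / +50 / -100 for ratios 1 / 0.5 / 2", {
  f <- fake_power_epochs(base_val = 2, interval_vals = c(2, 1, 4))
  idx <- erders_index(f$pow, f$ep, group_baseline(f$pow, f$ep, 1))
  expect_equal(unname(idx[1, 1, ]), c(0, 50, -100))
  raw <- erders_index(f$pow, f$ep, group_baseline(f$pow, f$ep, 1),
                      sign_convention = "raw_percent_change")
  expect_equal(unname(raw[1, 1, ]), c(0, -50, 100))
  # zero baseline -> missing, not a division blow-up
  f0 <- fake_power_epochs(0, c(1, 1, 1))
  expect_warning(idx0 <- erders_index(f0$pow, f0$ep, c(0, 0)), "P_base")
  expect_true(all(is.na(idx0)))
})

test_that("indices are invariant to channel-wise rescaling", {
  cfg <- tiny_config(seed = 23L)
  s <- simulate_session(cfg)
  rec <- bandpass_broad(s$recordings[[1]])
  ep <- epoch_extract(rec, s$events)
  m1 <- compute_erders(ep, s$behavior$type)
  ep$data[, 2, ] <- ep$data[, 2, ] * 3.7   # scale one channel
  m2 <- compute_erders(ep, s$behavior$type)
  for (k in names(m1$entries)) {
    expect_equal(m2$entries[[k]]$index, m1$entries[[k]]$index,
                 tolerance = 1e-6)
  }
})

test_that("recovered index matches 100*(1-g^2) and respects its sign", {
  res <- recovery_experiment(gains = c(0.6, 0.8, 1.0, 1.25),
                             n_trials = 160, seed = 5L)
  agg <- aggregate(recovered ~ gain + channel + window, res, mean)
  agg$expected <- 100 * (1 - agg$gain^2)
  expect_true(all(abs(agg$recovered - agg$expected) <= 5))
  mod <- agg[agg$gain != 1, ]
  expect_true(all(sign(mod$recovered) == sign(1 - mod$gain^2)))
})

test_that("a low-alpha-only modulation does not leak into other bands", {
  tab <- data.frame(type = performance_types(), band = "low_alpha",
                    window = "all", channel = "all", gain = 0.7)
  cfg <- simulation_config(n_subjects = 1, n_trials = 100, fs = 256,
                           channels = c("Cz", "Pz"),
                           inter_shot_mean = 14, inter_shot_jitter = 1,
                           amplitude_gain = tab, artifact_rate = 0,
                           quadrant_mix = uniform_mix(), seed = 29L)
  s <- simulate_session(cfg)
  ep <- epoch_extract(bandpass_broad(s$recordings[[1]]), s$events)
  maps <- compute_erders(ep, s$behavior$type)
  for (e in maps$entries) {
    if (e$band == "low_alpha") {
      expect_equal(mean(e$index), 51, tolerance = 5)
    } else {
      expect_true(all(abs(e$index) <= 8))
    }
  }
})

test_that("grand averages weight subjects equally and handle gaps", {
  mk_entry <- function(sub, ty, bd, mat, n) {
    list(subject = sub, type = ty, band = bd, index = mat,
         P_base = c(1, 1), n = n)
  }
  m <- matrix(1:6, 2, 3,
              dimnames = list(c("Cz", "Pz"), 1:3))
  maps <- structure(list(entries = list(
    `S01|Type1|theta` = mk_entry("S01", "Type1", "theta", m, 10),
    `S02|Type1|theta` = mk_entry("S02", "Type1", "theta", -m, 100),
    `S01|Type2|theta` = mk_entry("S01", "Type2", "theta", 2 * m, 10)),
    channel_labels = c("Cz", "Pz"), intervals = as.character(1:3),
    bands = "theta"), class = "erders_maps")
  g <- grand_average(maps)
  # m and -m cancel despite 10 vs 100 epochs (equal subject weight)
  expect_equal(g[["Type1|theta"]]$index, m * 0)
  expect_equal(g[["Type1|theta"]]$n_subjects, 2L)
  # single-subject type: grand average is the individual map
  expect_equal(g[["Type2|theta"]]$index, 2 * m)
  expect_equal(g[["Type2|theta"]]$n_subjects, 1L)
  expect_null(g[["Type3|theta"]])
})

test_that("windows before -5 s and inside the edge guard are rejected", {
  expect_error(analysis_windows(baseline = c(-5.5, -4.5)), "-5 s")
  expect_error(analysis_windows(baseline = c(-5, -4),
                                intervals = list(c(-4.5, -3.5))),
               "disjoint")
  f <- fake_power_epochs(1, c(1, 1, 1))
  expect_error(preshot:::window_indices(f$ep, c(-6, -5.8), 0.5),
               "edge guard")
})
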
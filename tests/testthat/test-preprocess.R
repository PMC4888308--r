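test_that("broadband filter matches its designed magnitude response", {
  fs <- 256
  t <- seq_len(20 * fs) / fs
  mid <- (5 * fs):(15 * fs)  # avoid filtfilt edge transients
  gain_at <- function(f_hz) {
    rec <- eeg_recording(matrix(sin(2 * pi * f_hz * t), 1), fs, "Cz")
    out <- bandpass_broad(rec)$data[1, ]
    sqrt(mean(out[mid]^2) / mean(sin(2 * pi * f_hz * t[mid])^2))
  }
  # oracle: squared magnitude (forward-backward) of the designed
  # Butterworth sections, from their frequency response
  nyq <- fs / 2
  hp <- signal::butter(4, 0.3 / nyq, "high")
  lp <- signal::butter(4, 40 / nyq, "low")
  H <- function(flt, w) {
    z <- exp(-1i * w * (seq_along(flt$b) - 1))
    zd <- exp(-1i * w * (seq_along(flt$a) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * zd))
  }
  design_gain <- function(f_hz) {
    w <- pi * f_hz / nyq
    (H(hp, w) * H(lp, w))^2   # squared: forward-backward application
  }
  g50 <- gain_at(50)
  expect_equal(g50, design_gain(50), tolerance = 0.05 * design_gain(50))
  expect_lt(20 * log10(g50), -15)          # 50 Hz strongly attenuated
  expect_equal(gain_at(10), 1, tolerance = 0.05)  # 10 Hz preserved
  # DC removed
  rec_dc <- eeg_recording(matrix(7.5, 1, 10 * fs), fs, "Cz")
  mid_dc <- (2 * fs):(8 * fs)
  expect_lt(max(abs(bandpass_broad(rec_dc)$data[1, mid_dc])), 1e-6)
  expect_error(bandpass_broad(rec_dc, high = 200), "Nyquist")
})

test_that("epoching is sample-exact and drops boundary events", {
  fs <- 256
  n <- 60 * fs
  onsets <- c(3, 10, 25, 40, 58)   # 3 s and 58 s lack full windows
  data <- matrix(0, 1, n)
  data[1, round(onsets * fs)] <- 100  # impulse at each shot sample
  rec <- eeg_recording(data, fs, "Cz")
  ev <- data.frame(subject = "S01", trial = seq_along(onsets),
                   onset_s = onsets)
  ep <- epoch_extract(rec, ev)
  expect_equal(dim(ep$data), c(3, 1, round(10 * fs)))
  expect_equal(ep$dropped$trial, c(1L, 5L))
  # the sample at relative time 0 is the shot-release sample
  for (i in 1:3) expect_equal(unname(ep$data[i, 1, ep$t0]), 100)
  expect_error(epoch_extract(rec, data.frame(subject = "S01", trial = 1,
                                             onset_s = 2)),
               "zero usable")
})

test_that("filtering commutes with epoching away from recording edges", {
  fs <- 256
  set.seed(31)
  x <- as.numeric(stats::filter(rnorm(40 * fs, 0, 10), rep(1, 4),
                                sides = 1))
  x[is.na(x)] <- 0
  rec <- eeg_recording(matrix(x, 1), fs, "Cz")
  ev <- data.frame(subject = "S01", trial = 1, onset_s = 20)
  a <- epoch_extract(bandpass_broad(rec), ev)$data[1, 1, ]
  ep_raw <- epoch_extract(rec, ev)
  seg <- eeg_recording(matrix(ep_raw$data[1, 1, ], 1), fs, "Cz")
  b <- bandpass_broad(seg)$data[1, ]
  guard <- round(1 * fs)
  inner <- guard:(length(a) - guard)
  expect_equal(a[inner], b[inner], tolerance = 0.02 * stats::sd(a[inner]))
})

test_that("threshold rules flag amplitude, gradient and flat channels", {
  fs <- 128
  ep <- epochs_from_signal(function(t) 10 * sin(2 * pi * 10 * t),
                           n_trials = 4, fs = fs)
  ep0 <- artifact_detect(ep)
  expect_equal(sum(ep0$artifact_bad), 0L)   # clean data: no rejections

  # amplitude artifact inside the pre-shot span of trial 2
  ep$data[2, 1, ep$t0 - (1:30)] <- 150
  # gradient artifact in trial 3
  ep$data[3, 2, ep$t0 - 200 + c(0, 1)] <- c(0, 80)
  # flatline channel in trial 4
  ep$data[4, 2, ] <- 0
  det <- artifact_detect(ep)
  expect_equal(det$artifact_bad, c(FALSE, TRUE, TRUE, TRUE))
  # idempotent
  expect_equal(artifact_detect(det)$artifact_bad, det$artifact_bad)

  # post-shot artifacts do not discard a trial
  ep2 <- epochs_from_signal(function(t) 10 * sin(2 * pi * 10 * t),
                            n_trials = 2, fs = fs)
  ep2$data[1, 1, ep2$t0 + (10:40)] <- 400
  expect_equal(sum(artifact_detect(ep2)$artifact_bad), 0L)

  flat <- epochs_from_signal(function(t) rep(0, length(t)), n_trials = 2,
                             fs = fs)
  expect_error(artifact_detect(flat), "all epochs rejected")
})

test_that("injected artifacts are recovered by detection (recall >= 0.9)", {
  cfg <- simulation_config(
    n_subjects = 1, n_trials = 40, fs = 128,
    channels = c("Fp1", "Fpz", "Fp2", "Fz", "Cz", "Pz", "O1", "O2"),
    inter_shot_mean = 14, inter_shot_jitter = 1, artifact_rate = 4,
    seed = 19L)
  s <- simulate_session(cfg)
  rec <- bandpass_broad(s$recordings[[1]])
  ep <- artifact_detect(epoch_extract(rec, s$events))
  log <- s$artifact_log
  # injected artifacts whose bulk lies in an epoch's pre-shot span
  hit <- overlap <- 0
  for (i in seq_len(nrow(log))) {
    c_art <- log$onset_s[i] + log$duration_s[i] / 2
    j <- which(ep$trials$onset_s - 6 <= c_art &
                 c_art <= ep$trials$onset_s)
    if (length(j) == 1L) {
      overlap <- overlap + 1
      hit <- hit + ep$artifact_bad[j]
    }
  }
  expect_gt(overlap, 5)
  expect_gte(hit / overlap, 0.9)
  # retained-count bookkeeping
  expect_equal(ep$rejections$n_rejected, sum(ep$artifact_bad))
})
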
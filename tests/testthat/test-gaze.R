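test_that("median smoothing matches the shrinking-window oracle", {
  set.seed(1)
  n <- 200
  rec <- gaze_recording(t = (0:(n - 1)) / 500, x = cumsum(rnorm(n, sd = 0.3)),
                        y = rnorm(n), fs = 500)
  sm <- smooth_gaze(rec)
  expect_equal(sm$x, oracle_running_median(rec$x, 21), tolerance = 1e-12)
  expect_equal(sm$y, oracle_running_median(rec$y, 21), tolerance = 1e-12)
  # constant trace unchanged; isolated spike removed
  recc <- gaze_recording(t = (0:99) / 500, x = rep(2, 100), y = rep(-1, 100),
                         fs = 500)
  expect_equal(smooth_gaze(recc)$x, rep(2, 100))
  spk <- recc; spk$x[50] <- 12
  expect_equal(smooth_gaze(spk)$x, rep(2, 100))
  expect_error(smooth_gaze(gaze_recording(t = 0:5 / 500, x = rep(0, 6),
                                          y = rep(0, 6), fs = 500)),
               "too short")
})

test_that("angular velocity matches the finite-difference oracle", {
  # stationary and linear-drift cases
  n <- 100; fs <- 500
  still <- gaze_recording(t = (0:(n - 1)) / fs, x = rep(1, n), y = rep(0, n),
                          fs = fs)
  expect_equal(angular_velocity(still), rep(0, n))
  drift <- gaze_recording(t = (0:(n - 1)) / fs, x = (0:(n - 1)) / fs,
                          y = rep(0, n), fs = fs)
  expect_equal(angular_velocity(drift), rep(1, n), tolerance = 1e-9)
  set.seed(2)
  rnd <- gaze_recording(t = (0:(n - 1)) / fs, x = rnorm(n), y = rnorm(n),
                        fs = fs)
  v <- angular_velocity(rnd)
  vo <- c(NA, sqrt(diff(rnd$x)^2 + diff(rnd$y)^2) * fs); vo[1] <- vo[2]
  expect_equal(v, vo, tolerance = 1e-12)
})

test_that("threshold detector finds a clean 5-degree saccade exactly once", {
  tr <- make_saccade_trace(5, noise_sd = 0)
  v <- angular_velocity(tr$rec)
  expect_gt(max(v, na.rm = TRUE), 250)  # main-sequence-like peak velocity
  ev <- detect_saccades_thresholds(tr$rec)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$saccade_onset - tr$onsets), 0.010)
  expect_equal(ev$amplitude, 5, tolerance = 0.05)
})

test_that("sub-threshold drift produces no saccades", {
  n <- 2000; fs <- 500
  drift <- gaze_recording(t = (0:(n - 1)) / fs, x = 0.5 * (0:(n - 1)) / fs,
                          y = rep(0, n), fs = fs)
  expect_equal(nrow(detect_saccades_thresholds(drift)), 0)
})

test_that("threshold detector matches generator ground truth on 100+ events", {
  cfg <- synth_config(seed = 77, duration_s = 60, blink_rate_hz = 0)
  gz <- generate_gaze(cfg)
  tr <- gz$truth$events
  ev <- detect_saccades_thresholds(gz$gaze)
  err <- vapply(tr$saccade_onset, function(t0)
    min(abs(ev$saccade_onset - t0)), numeric(1))
  expect_gte(mean(err <= 0.010), 0.97)
  fp <- vapply(ev$saccade_onset, function(t0)
    min(abs(tr$saccade_onset - t0)), numeric(1))
  expect_lte(mean(fp > 0.020), 0.01)
  # events are non-overlapping and time-ordered
  expect_true(all(diff(ev$saccade_onset) > 0))
  expect_true(all(ev$saccade_offset[-nrow(ev)] <= ev$saccade_onset[-1]))
})

test_that("morphological closing follows dilate-then-erode semantics", {
  # runs separated by a gap smaller than the kernel merge; larger gaps survive
  m <- rep(FALSE, 40)
  m[10:12] <- TRUE; m[15:17] <- TRUE   # 2-sample gap
  m[25:26] <- TRUE; m[37:38] <- TRUE   # 10-sample gap
  cl <- fixnov:::close1d(m, 5)
  expect_true(all(cl[10:17]))
  expect_false(any(cl[28:35]))
  set.seed(3)
  for (i in 1:20) {
    r <- runif(60) < 0.3
    expect_identical(fixnov:::close1d(r, 5), oracle_close(r, 5))
  }
})

test_that("the 2-SD detector handles invalid data and finds saccade runs", {
  expect_error(detect_saccades_sd(
    gaze_recording(t = 0:99 / 500, x = rep(NA_real_, 100),
                   y = rep(NA_real_, 100), valid = rep(FALSE, 100),
                   fs = 500)), "no valid samples")
  tr <- make_saccade_trace(c(6, 4, 8), noise_sd = 0.02)
  mask <- detect_saccades_sd(smooth_gaze(tr$rec))
  runs <- fixnov:::true_runs(mask)
  expect_equal(nrow(runs), 3)
})

test_that("fixation onset follows the 70th-percentile rule", {
  # step profile: constant high velocity (50 samples) then exact zero; the
  # 70th percentile of the window equals the plateau value, so the strict
  # "<" rule selects the first zero-velocity sample after the saccade
  fs <- 500
  n0 <- 20; nr <- 50; n1 <- 70
  # step 0.125 deg (a power of two) keeps the plateau velocity bit-exact
  x <- c(rep(0, n0), (1:nr) * 0.125, rep(nr * 0.125, n1))
  nn <- length(x)
  rec <- gaze_recording(t = (0:(nn - 1)) / fs, x = x, y = numeric(nn),
                        fs = fs)
  on <- (n0 - 0.5) / fs
  fo <- fixation_onset(rec, saccade_onset = on)
  v <- angular_velocity(rec)
  expect_equal(fo, rec$t[which(rec$t > on & v == 0)[1]])
  # brute-force percentile + scan oracle on random traces
  set.seed(4)
  for (i in 1:20) {
    n <- 200
    rr <- gaze_recording(t = (0:(n - 1)) / fs, x = cumsum(rnorm(n, sd = 0.05)),
                         y = numeric(n), fs = fs)
    on <- runif(1, 0.05, 0.2)
    v <- angular_velocity(rr)
    w <- v[rr$t >= on - 0.033 & rr$t <= on + 0.120]
    p70 <- quantile(w, 0.7, type = 7, names = FALSE)
    cand <- which(rr$t > on & v < p70)
    expected <- if (length(cand)) rr$t[cand[1]] else NA_real_
    expect_identical(fixation_onset(rr, on), expected)
  }
})

test_that("sd-detector fixation onsets land within 10 ms of ground truth", {
  cfg <- synth_config(seed = 78, duration_s = 60, blink_rate_hz = 0)
  gz <- generate_gaze(cfg)
  ev <- detect_saccades_sd_events(gz$gaze)
  tr <- gz$truth$events
  err <- vapply(tr$fixation_onset, function(t0)
    min(abs(ev$fixation_onset - t0)), numeric(1))
  expect_gte(mean(err <= 0.010), 0.95)
})

test_that("exclusion rules match a hand-enumerated fixture and are idempotent", {
  fs <- 500
  n <- 5 * fs
  valid <- rep(TRUE, n)
  valid[round(2.0 * fs):round(2.1 * fs)] <- FALSE  # blink at 2.0-2.1 s
  rec <- gaze_recording(t = (0:(n - 1)) / fs, x = numeric(n), y = numeric(n),
                        valid = valid, fs = fs)
  ev <- data.frame(
    saccade_onset  = c(0.50, 0.80, 1.00, 1.30, 1.95, 2.15, 2.50, 3.00, 3.111, 4.00),
    saccade_offset = c(0.53, 0.83, 1.03, 1.33, 1.98, 2.18, 2.53, 3.03, 3.141, 4.03))
  ev$fixation_onset <- ev$saccade_offset
  ev$fixation_duration <- c(diff(ev$saccade_onset), NA) - 0.03
  ev$amplitude <- 5; ev$quality_ok <- TRUE
  out <- apply_exclusions(ev, rec)
  # hand enumeration:
  #  row 2: preceding fixation 0.80-0.53 = 0.27 -> kept
  #  row 3: 1.00-0.83 = 0.17 -> kept; row 4: 1.30-1.03 = 0.27 -> kept
  #  row 5: saccade 1.95-1.98, blink starts 2.0 (within 83 ms) -> dropped
  #  row 6: saccade 2.15-2.18, blink ends 2.1 (within 83 ms) -> dropped
  #  row 7: 2.50 vs fix onset 2.18: 0.32 -> kept (blink 0.32 s away > 83 ms)
  #  row 9: 3.111 - 3.03 = 0.081 < 0.110 -> dropped
  #  row 10: 4.00 - 3.141 = 0.859 -> kept
  expect_equal(out$saccade_onset, c(0.50, 0.80, 1.00, 1.30, 2.50, 3.00, 4.00))
  expect_identical(apply_exclusions(out, rec), out)
})

test_that("the preceding-fixation threshold is strict at 110 ms", {
  fs <- 500; n <- 3 * fs
  rec <- gaze_recording(t = (0:(n - 1)) / fs, x = numeric(n), y = numeric(n),
                        fs = fs)
  base <- data.frame(saccade_onset = 1.0, saccade_offset = 1.03,
                     fixation_onset = 1.03, fixation_duration = NA,
                     amplitude = 1, quality_ok = TRUE)
  for (gap in c(0.109, 0.111)) {
    ev <- rbind(base, data.frame(saccade_onset = 1.03 + gap,
                                 saccade_offset = 1.06 + gap,
                                 fixation_onset = 1.06 + gap,
                                 fixation_duration = NA, amplitude = 1,
                                 quality_ok = TRUE))
    out <- apply_exclusions(ev, rec)
    if (gap < 0.110) expect_equal(nrow(out), 1) else expect_equal(nrow(out), 2)
  }
})

test_that("saccade amplitude is the 2-norm of the gaze change", {
  fs <- 500; n <- 200
  x <- c(rep(0, 100), rep(3, 100)); y <- c(rep(0, 100), rep(4, 100))
  rec <- gaze_recording(t = (0:(n - 1)) / fs, x = x, y = y, fs = fs)
  expect_equal(saccade_amplitude(rec, 0.19, 0.21), 5)
  expect_equal(saccade_amplitude(rec, 0.05, 0.1), 0)
  set.seed(5)
  rnd <- gaze_recording(t = (0:(n - 1)) / fs, x = rnorm(n), y = rnorm(n),
                        fs = fs)
  for (i in 1:10) {
    i0 <- sample(10:90, 1); i1 <- i0 + sample(5:40, 1)
    a <- saccade_amplitude(rnd, rnd$t[i0], rnd$t[i1])
    expect_equal(a, sqrt((rnd$x[i1] - rnd$x[i0])^2 +
                         (rnd$y[i1] - rnd$y[i0])^2), tolerance = 1e-12)
  }
})
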
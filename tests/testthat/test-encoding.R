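test_that("impulse trains place pulses at the nearest sample", {
  tr <- impulse_train(c(0.5, 1.0, 2.0), duration = 3, fs = 100)
  expect_equal(sum(tr), 3)
  expect_equal(tr[101], 1)  # event exactly at a sample time
  # round-half-even at 100 Hz: 1.004 s -> sample 100 (0-based), index 101
  tr2 <- impulse_train(1.004, duration = 3, fs = 100)
  expect_equal(which(tr2 > 0) - 1L, 100L)
  # 1.005 rounds to the even sample 100 as well; 1.0051 rounds up
  expect_equal(which(impulse_train(1.0051, 3, 100) > 0) - 1L, 101L)
  # NA heights drop the event
  tr3 <- impulse_train(c(0.5, 1), 2, 100, heights = c(NA, 2))
  expect_equal(sum(tr3 != 0), 1)
  expect_error(impulse_train(5, duration = 3, fs = 100), "within")
})

test_that("B-spline expansion has 5 columns, sums to one, and matches Cox-de Boor", {
  set.seed(31)
  v <- rgamma(300, 3, 1)
  B <- bspline_expand(v, n = 5)
  expect_equal(ncol(B), 5)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-9)
  knots <- attr(B, "knots")
  # interior knot at the median
  expect_equal(knots[5], median(v), tolerance = 1e-9)
  xs <- runif(100, min(v), max(v))
  Bx <- bspline_expand(xs, n = 5, knots = knots)
  for (i in 1:5) {
    oracle <- oracle_bspline(xs, knots, i, 4)
    # Cox-de Boor half-open intervals differ only at the right boundary
    inner <- xs < max(v)
    expect_equal(Bx[inner, i], oracle[inner], tolerance = 1e-9)
  }
  expect_error(bspline_expand(rep(1, 10), n = 5), "distinct values")
})

test_that("lagged designs have the stated shape and reproduce convolutions", {
  fs <- 100
  reg <- impulse_train(c(1, 2.5), 4, fs)
  des <- build_design(list(ev = reg), c(-0.2, 0.6), fs)
  expect_equal(ncol(des$X), 81)       # inclusive endpoints at 100 Hz
  expect_equal(length(des$lags), 81)
  # single pulse: each lag column is the shifted pulse
  one <- impulse_train(1, 3, fs)
  d1 <- build_design(list(ev = one), c(-0.1, 0.1), fs)
  for (j in seq_along(d1$lag_samples)) {
    expected <- numeric(300)
    expected[101 + d1$lag_samples[j]] <- 1
    expect_equal(d1$X[, j], expected)
  }
  # predicted signal from known weights equals event summation
  set.seed(32)
  w <- rnorm(81)
  pred <- des$X %*% w
  oracle <- oracle_event_summation(which(reg != 0), reg[reg != 0], w,
                                   des$lag_samples, length(reg))
  expect_equal(as.numeric(pred), oracle, tolerance = 1e-12)
})

test_that("banded ridge with equal penalties equals the normal-equation oracle", {
  set.seed(33)
  X <- matrix(rnorm(400 * 30), 400)
  y <- rnorm(400)
  bands <- list(a = 1:10, b = 11:30)
  for (lam in c(0.1, 1, 50)) {
    w <- ridge_fit(X, y, c(lam, lam), bands)
    expect_lt(max(abs(w - oracle_ridge(X, y, lam))), 1e-8)
  }
  # exact ridge optimality: gradient norm of the banded objective
  lam <- c(2, 37)
  w <- ridge_fit(X, y, lam, bands)
  pen <- numeric(30); pen[bands$a] <- lam[1]; pen[bands$b] <- lam[2]
  grad <- -2 * crossprod(X, y - X %*% w) + 2 * pen * w
  expect_lt(sqrt(sum(grad^2)), 1e-6 * sqrt(sum(crossprod(X, y)^2)))
})

test_that("extreme penalties shrink a band to zero; tiny penalties recover truth", {
  set.seed(34)
  X <- matrix(rnorm(500 * 20), 500)
  w_true <- c(rnorm(10), rep(0, 10))
  y <- X %*% w_true
  bands <- list(a = 1:10, b = 11:20)
  w <- ridge_fit(X, y, c(1e-8, 1e12), bands)
  expect_lt(sqrt(sum(w[11:20]^2)), 1e-6)
  expect_lt(max(abs(w[1:10] - w_true[1:10])) / max(abs(w_true[1:10])), 1e-4)
  expect_error(ridge_fit(X, y, c(0, 1), bands), "> 0")
})

test_that("cross-validated r matches a brute-force fold oracle", {
  toy <- make_encoding_toy(seed = 35, dur = 40, n_ev = 100)
  hier <- list(regressor_spec("fixation", "fixation_onset", "impulse"))
  lam <- 5
  m <- fit_trf(toy$events, NULL, toy$y, fs = toy$fs, trials = 4,
               hierarchy = hier, lambda = lam, stages = TRUE)
  # oracle: explicit per-fold fit with training-fold scaling and centering
  reg <- impulse_train(toy$events$fixation_onset, toy$dur, toy$fs)
  des <- build_design(list(fixation = reg), c(-0.2, 0.6), toy$fs)
  n <- nrow(des$X)
  fold <- as.integer(cut(seq_len(n), 4, labels = FALSE))
  y <- as.numeric(toy$y)
  r_oracle <- sapply(1:4, function(f) {
    tr <- fold != f
    xm <- colMeans(des$X[tr, ])
    s <- apply(des$X[tr, ], 2, function(col)
      sqrt(mean(col^2) - mean(col)^2))
    s[s < 1e-12] <- 1
    Xs <- sweep(sweep(des$X, 2, xm), 2, s, "/")
    w <- oracle_ridge(Xs[tr, ], y[tr] - mean(y[tr]), lam)
    cor(Xs[!tr, ] %*% w, y[!tr])
  })
  expect_equal(unname(m$r_per_stage[1, 1]), mean(r_oracle), tolerance = 1e-8)
  expect_equal(unname(m$r_fold_stage[[1]][, 1]), r_oracle, tolerance = 1e-8)
})

test_that("held-out predictions never use held-out statistics", {
  # replace fold 2's responses: fold 2's model is trained on folds 1/3/4,
  # which are unchanged, so its held-out r must equal the oracle built from
  # the *unchanged* training data evaluated against the new fold-2 responses
  toy <- make_encoding_toy(seed = 36, dur = 40, n_ev = 100)
  hier <- list(regressor_spec("fixation", "fixation_onset", "impulse"))
  lam <- 5
  n <- ncol(toy$y)
  fold <- as.integer(cut(seq_len(n), 4, labels = FALSE))
  set.seed(1)
  y2 <- toy$y
  y2[1, fold == 2] <- rnorm(sum(fold == 2))
  m2 <- fit_trf(toy$events, NULL, y2, fs = toy$fs, trials = 4,
                hierarchy = hier, lambda = lam, stages = TRUE)
  reg <- impulse_train(toy$events$fixation_onset, toy$dur, toy$fs)
  des <- build_design(list(fixation = reg), c(-0.2, 0.6), toy$fs)
  tr <- fold != 2
  y_tr <- as.numeric(toy$y)[tr]           # original training responses
  xm <- colMeans(des$X[tr, ])
  s <- apply(des$X[tr, ], 2, function(col) sqrt(mean(col^2) - mean(col)^2))
  s[s < 1e-12] <- 1
  Xs <- sweep(sweep(des$X, 2, xm), 2, s, "/")
  w <- oracle_ridge(Xs[tr, ], y_tr - mean(y_tr), lam)
  r_oracle <- as.numeric(cor(Xs[!tr, ] %*% w, y2[1, !tr]))
  expect_equal(unname(m2$r_fold_stage[[1]][2, 1]), r_oracle,
               tolerance = 1e-8)
})

test_that("the sequential search matches an exhaustive sweep and breaks ties low", {
  toy <- make_encoding_toy(seed = 37, dur = 40, n_ev = 100)
  hier <- list(regressor_spec("fixation", "fixation_onset", "impulse"))
  grid <- 10^seq(-1, 3, length.out = 5)
  m <- fit_trf(toy$events, NULL, toy$y, fs = toy$fs, trials = 4,
               hierarchy = hier, lambda_grid = grid)
  sweep_r <- sapply(grid, function(l) {
    mm <- fit_trf(toy$events, NULL, toy$y, fs = toy$fs, trials = 4,
                  hierarchy = hier, lambda = l, stages = TRUE)
    mean(mm$r_per_stage[, 1])
  })
  expect_equal(unname(m$lambda[1]), grid[which.max(sweep_r)])
  # an all-zero feature band gives identical scores for every lambda: tie
  # resolved to the smallest grid value
  ft <- data.frame(zeros = rep(0, nrow(toy$events)))
  hier2 <- c(hier, list(regressor_spec("zeros", "fixation_onset", "linear")))
  m2 <- fit_trf(toy$events, ft, toy$y, fs = toy$fs, trials = 4,
                hierarchy = hier2, lambda_grid = grid)
  expect_equal(unname(m2$lambda[2]), min(grid))
})

test_that("Delta r telescopes and a duplicated feature adds nothing", {
  cfg <- synth_config(seed = 38, duration_s = 120, snr = 1, n_channels = 4,
                      n_modulated = 4, blink_rate_hz = 0)
  gz <- generate_gaze(cfg)
  ft <- generate_feature_table(cfg, gz$truth)
  ft$novelty2 <- ft$novelty
  rec <- generate_neural(cfg, gz$truth, ft, bands = c("fixation", "novelty"))
  hier <- list(regressor_spec("fixation", "fixation_onset", "impulse"),
               regressor_spec("novelty", "fixation_onset", "linear"),
               regressor_spec("novelty2", "fixation_onset", "linear"))
  m <- fit_trf(gz$truth$events, ft, rec, trials = 8, hierarchy = hier,
               lambda = c(1, 10, 10), stages = TRUE)
  # telescoping: r(final) = r(stage 1) + sum of Delta r
  final <- m$r_per_stage[, 3]
  expect_equal(final, m$r_per_stage[, 1] + m$delta_r[, 2] + m$delta_r[, 3],
               tolerance = 1e-12)
  expect_gt(mean(m$delta_r[, "novelty"]), 0.01)
  expect_lt(max(abs(m$delta_r[, "novelty2"])), 0.005)
})

test_that("TRFs recover ground truth and spline bands reconstruct responses", {
  cfg <- synth_config(seed = 39, duration_s = 180, snr = 2, n_channels = 3,
                      n_modulated = 3, blink_rate_hz = 0)
  gz <- generate_gaze(cfg)
  ft <- generate_feature_table(cfg, gz$truth)
  rec <- generate_neural(cfg, gz$truth, ft, bands = c("fixation", "novelty"))
  tr <- attr(rec, "truth")
  hier <- list(regressor_spec("fixation", "fixation_onset", "impulse"),
               regressor_spec("novelty", "fixation_onset", "linear"))
  m <- fit_trf(gz$truth$events, ft, rec, trials = 8, hierarchy = hier,
               lambda = c(1, 1), stages = FALSE)
  for (b in c("fixation", "novelty")) {
    w <- extract_trf(m, b)
    for (c in 1:3)
      expect_gt(cor(w[c, ], tr$true_trfs[b, c, ]), 0.95)
  }
  # noiseless impulse band: near-exact recovery at tiny penalty
  cfg0 <- synth_config(seed = 40, duration_s = 120, noise_sd = 0,
                       n_channels = 2, n_modulated = 2, blink_rate_hz = 0)
  gz0 <- generate_gaze(cfg0)
  ft0 <- generate_feature_table(cfg0, gz0$truth)
  rec0 <- generate_neural(cfg0, gz0$truth, ft0, bands = "fixation")
  m0 <- fit_trf(gz0$truth$events, ft0, rec0, trials = 4,
                hierarchy = list(regressor_spec("fixation", "fixation_onset",
                                                "impulse")),
                lambda = 1e-6, stages = FALSE)
  w0 <- extract_trf(m0, "fixation")
  t0 <- attr(rec0, "truth")$true_trfs["fixation", , ]
  expect_lt(max(abs(w0 - t0)), 1e-4)
})

test_that("spline amplitude bands reproduce the 5-column structure end to end", {
  cfg <- synth_config(seed = 41, duration_s = 90, snr = 2, n_channels = 2,
                      n_modulated = 2, blink_rate_hz = 0)
  gz <- generate_gaze(cfg)
  ft <- generate_feature_table(cfg, gz$truth)
  rec <- generate_neural(cfg, gz$truth, ft, bands = c("fixation", "amplitude"))
  hier <- list(regressor_spec("fixation", "fixation_onset", "impulse"),
               regressor_spec("amplitude", "saccade_onset", "bspline"))
  m <- fit_trf(gz$truth$events, ft, rec, trials = 6, lambda = c(1, 1),
               hierarchy = hier, stages = FALSE)
  arr <- extract_trf(m, "amplitude")
  expect_equal(dim(arr)[2], 5)
  rc <- extract_trf(m, "amplitude", at_values = c(2, 8))
  expect_equal(dim(rc), c(2, 2, length(m$lags)))
})

test_that("model methods (print, coef, predict, residuals, simulate) are coherent", {
  toy <- make_encoding_toy(seed = 42, dur = 40, n_ev = 100, noise_sd = 0.2)
  hier <- list(regressor_spec("fixation", "fixation_onset", "impulse"))
  m <- fit_trf(toy$events, NULL, toy$y, fs = toy$fs, trials = 4,
               hierarchy = hier, lambda = 1, stages = FALSE)
  expect_output(print(m), "trf_model")
  expect_named(coef(m), "fixation")
  pred <- predict(m)
  expect_equal(dim(pred), dim(toy$y))
  expect_gt(cor(pred[1, ], toy$clean), 0.9)
  res <- residuals(m)
  expect_equal(pred + res, toy$y, tolerance = 1e-12)
  sims <- simulate(m, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(toy$y))
})

test_that("alignment comparison favors the generating alignment", {
  cfg <- synth_config(seed = 43, duration_s = 180, snr = 1, n_channels = 3,
                      n_modulated = 3, blink_rate_hz = 0)
  gz <- generate_gaze(cfg)
  ft <- generate_feature_table(cfg, gz$truth)
  rec <- generate_neural(cfg, gz$truth, ft, bands = c("fixation", "novelty"))
  cmp <- compare_alignments(gz$truth$events, ft, rec, trials = 6)
  fix_r <- cmp$r[cmp$alignment == "fixation" &
                 cmp$variant == "onset+amplitude+novelty"]
  sac_r <- cmp$r[cmp$alignment == "saccade" &
                 cmp$variant == "onset+amplitude+novelty"]
  expect_gte(fix_r, sac_r - 0.02)
  # zero saccade duration: alignments coincide, results identical
  ev2 <- gz$truth$events
  ev2$fixation_onset <- ev2$saccade_onset
  cmp2 <- compare_alignments(ev2, ft, rec, trials = 6)
  expect_equal(cmp2$r[cmp2$alignment == "saccade"],
               cmp2$r[cmp2$alignment == "fixation"], tolerance = 1e-10)
})
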
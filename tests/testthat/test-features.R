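geom64 <- screen_geometry(width_px = 640, height_px = 480, width_cm = 40,
                          height_cm = 30, viewing_distance_cm = 57)

test_that("pixels per degree matches the small-angle trigonometric oracle", {
  ppd <- pixels_per_degree(geom64)
  per_cm <- mean(c(640 / 40, 480 / 30))
  expect_equal(ppd, 2 * 57 * tan(0.5 * pi / 180) * per_cm, tolerance = 1e-12)
})

test_that("patch extraction preserves uniform frames and central markers", {
  frame <- array(0.3, dim = c(480, 640, 3))
  p <- extract_patch(frame, c(320, 240), geom64, out_res = 50)
  expect_true(p$valid)
  expect_true(all(abs(p$pixels - 0.3) < 1e-9))
  # centered marker stays centered in the patch
  frame2 <- frame
  frame2[238:242, 318:322, ] <- 1
  p2 <- extract_patch(frame2, c(320, 240), geom64, out_res = 51)
  ctr <- p2$pixels[24:28, 24:28, 1]
  expect_gt(mean(ctr), mean(p2$pixels[1:5, 1:5, 1]))
  expect_equal(which.max(apply(p2$pixels[, , 1], 1, max)), 26, tolerance = 1)
  # off-screen gaze: invalid patch, not an error
  p3 <- extract_patch(frame, c(-50, 240), geom64)
  expect_false(p3$valid)
})

test_that("white, black, and constant patches give canonical color statistics", {
  white <- array(1, dim = c(8, 8, 3))
  f <- luminance_color_features(white)
  expect_equal(unname(f["luminance"]), 100, tolerance = 1e-6)
  expect_equal(unname(f["a_mean"]), 0, tolerance = 1e-6)
  expect_equal(unname(f["b_mean"]), 0, tolerance = 1e-6)
  expect_equal(unname(f[c("luminance_skew", "luminance_kurtosis")]),
               c(0, 0))
  black <- array(0, dim = c(8, 8, 3))
  expect_equal(unname(luminance_color_features(black)["luminance"]), 0,
               tolerance = 1e-6)
})

test_that("contrast features behave on degenerate and structured patches", {
  const <- matrix(0.5, 20, 20)
  f <- contrast_energy_features(const)
  expect_equal(unname(f["michelson"]), 0)
  expect_equal(unname(f["rms_contrast"]), 0)
  expect_equal(unname(f["orientation_bias"]), 0)
  cb <- matrix(rep(c(0, 1), 162)[1:324], 18, 18)
  expect_equal(unname(contrast_energy_features(cb)["michelson"]), 1)
  # vertical grating: strong vertical energy, near-zero horizontal
  vg <- matrix(rep(sin(seq(0, 8 * pi, length.out = 32)) / 2 + 0.5,
                   times = 32), 32, 32, byrow = TRUE)
  fg <- contrast_energy_features(vg)
  expect_gt(unname(fg["orientation_bias"]), 0.9)
  expect_lt(unname(fg["horizontal_energy"]),
            0.01 * unname(fg["vertical_energy"]))
})

test_that("spectrum slope recovers the construction exponent", {
  set.seed(11)
  ppd <- 64 / 5
  for (alpha in c(1.0, 1.5)) {
    sl <- replicate(15, suppressWarnings(
      spectrum_slope(synth_texture(64, alpha), ppd)))
    expect_lt(abs(mean(sl) - alpha), 0.1)
  }
  white <- replicate(15, suppressWarnings(
    spectrum_slope(matrix(runif(64 * 64), 64), ppd)))
  expect_lt(abs(mean(white)), 0.15)
  # invariant to multiplicative intensity scaling
  tex <- synth_texture(64, 1)
  expect_equal(suppressWarnings(spectrum_slope(tex, ppd)),
               suppressWarnings(spectrum_slope(tex * 0.5, ppd)),
               tolerance = 1e-9)
  expect_error(spectrum_slope(matrix(0.5, 8, 8), ppd), "too small")
})

test_that("GLCM features equal brute-force co-occurrence counting", {
  set.seed(12)
  q <- matrix(sample(1:4, 36, replace = TRUE), 6, 6)
  g <- (q - 1) / 4 + 1e-3  # quantizes back to levels 1..4 of 4
  got <- glcm_features(g, levels = 4L)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  oracle <- rowMeans(sapply(offs, function(o) oracle_glcm_dir(q, 4, o[1], o[2])))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  # constant-patch conventions
  cc <- texture_shape_features(matrix(0.5, 16, 16))
  expect_equal(unname(cc["glcm_contrast"]), 0)
  expect_equal(unname(cc["glcm_homogeneity"]), 1)
  expect_equal(unname(cc["glcm_asm"]), 1)
  expect_equal(unname(cc["blob_count"]), 0)
})

test_that("a filled disk yields one nearly-solid round blob", {
  m <- matrix(0, 50, 50)
  cc <- as.matrix(expand.grid(1:50, 1:50))
  m[cc[(cc[, 1] - 25)^2 + (cc[, 2] - 25)^2 <= 144, ]] <- 1
  f <- texture_shape_features(m)
  expect_equal(unname(f["blob_count"]), 1)
  expect_gt(unname(f["blob_solidity"]), 0.9)
  expect_lt(unname(f["blob_eccentricity"]), 0.2)
})

test_that("saliency features vanish on uniform frames and ignore achromatic contrast", {
  uniform <- array(0.5, dim = c(128, 128, 3))
  s <- saliency_features(uniform, c(64, 64))
  expect_length(s, 29)  # 28 center-surround values + the plugin column
  expect_lt(max(abs(s[1:28])), 1e-9)
  expect_true(is.na(s["sal_external"]))
  disk <- uniform
  for (i in 1:128) for (j in 1:128)
    if ((i - 64)^2 + (j - 64)^2 < 100) disk[i, j, ] <- 1
  s2 <- saliency_features(disk, c(64, 64))
  expect_gt(max(s2[1:6]), 0.01)             # intensity center-surround
  expect_lt(max(abs(s2[7:18])), 1e-9)       # no color opponency
})

test_that("optical flow feature averages the pre-saccadic window", {
  # static video
  flow0 <- array(0, dim = c(5, 12, 12, 2))
  expect_equal(optical_flow_feature(flow0, (0:4) / 10, c(1, 100, 1, 100), 0.45),
               0)
  expect_equal(optical_flow_feature(NULL, NULL, NULL, 1), 0)
  # global 2 px/frame translation
  flow2 <- array(0, dim = c(5, 12, 12, 2)); flow2[, , , 1] <- 2
  expect_equal(optical_flow_feature(flow2, (0:4) / 10, c(1, 100, 1, 100), 0.45),
               2)
  # window straddling a motion onset: frame-weighted mean oracle
  flow3 <- array(0, dim = c(5, 12, 12, 2))
  flow3[4:5, , , 1] <- 3  # motion starts at frame 4 (t = 0.3)
  got <- optical_flow_feature(flow3, (0:4) / 10, c(1, 100, 1, 100), 0.55)
  # window [0.30, 0.50] covers frames at t = 0.3, 0.4 -> both moving
  expect_equal(got, 3)
  got2 <- optical_flow_feature(flow3, (0:4) / 10, c(1, 100, 1, 100), 0.45)
  # window [0.20, 0.40] covers frames at t = 0.2 (0) and 0.3, 0.4 (3)
  expect_equal(got2, 2)
  # window before recording start -> missing
  expect_true(is.na(optical_flow_feature(flow3, (0:4) / 10 + 10,
                                         c(1, 100, 1, 100), 0.45)))
})

test_that("patch embedding is deterministic and resize preserves ramps", {
  enc <- toy_encoder()
  tex <- synth_texture(64, 1)
  e1 <- embed_patch(tex, enc); e2 <- embed_patch(tex, enc)
  expect_identical(e1$vector, e2$vector)
  ramp <- matrix(rep(seq(0, 1, length.out = 100), each = 100), 100, 100)
  big <- fixnov:::resize_cubic(ramp, 224)
  target <- matrix(rep(seq(0, 1, length.out = 224), each = 224), 224, 224)
  expect_lt(max(abs(big - target)), 0.01)
})

test_that("novelty is the cosine distance with its analytic special cases", {
  e <- function(v) structure(list(vector = v, encoder_id = "x"),
                             class = "patch_embedding")
  expect_equal(novelty(e(c(1, 0)), e(c(2, 0))), 0)
  expect_equal(novelty(e(c(1, 0)), e(c(0, 3))), 1)
  expect_equal(novelty(e(c(1, 1)), e(c(-2, -2))), 2)
  # symmetry and positive-scale invariance
  set.seed(13)
  a <- rnorm(16); b <- rnorm(16)
  expect_equal(novelty(e(a), e(b)), novelty(e(b), e(a)))
  expect_equal(novelty(e(a), e(b)), novelty(e(3 * a), e(0.2 * b)),
               tolerance = 1e-12)
  expect_error(novelty(e(c(0, 0)), e(c(1, 0))), "zero-norm")
  e2 <- structure(list(vector = a, encoder_id = "y"),
                  class = "patch_embedding")
  expect_error(novelty(e(a), e2), "different encoders")
})

test_that("feature clustering orders duplicated and planted-block columns together", {
  set.seed(14)
  n <- 5000
  base <- rnorm(n)
  tab <- data.frame(a = base, b = base, c = rnorm(n))
  res <- feature_correlation_clustering(tab)
  ia <- match("a", res$order); ib <- match("b", res$order)
  expect_equal(abs(ia - ib), 1)
  expect_equal(res$R["a", "b"], 1)
  # independent Gaussian columns: small off-diagonal correlations
  ind <- as.data.frame(matrix(rnorm(n * 4), n))
  R <- feature_correlation_clustering(ind)$R
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
  # two planted blocks come out contiguous
  z1 <- rnorm(n); z2 <- rnorm(n)
  blocks <- data.frame(p1 = z1 + 0.3 * rnorm(n), p2 = z1 + 0.3 * rnorm(n),
                       p3 = z1 + 0.3 * rnorm(n), q1 = z2 + 0.3 * rnorm(n),
                       q2 = z2 + 0.3 * rnorm(n), q3 = z2 + 0.3 * rnorm(n))
  ord <- feature_correlation_clustering(blocks)$order
  pos_p <- sort(match(c("p1", "p2", "p3"), ord))
  pos_q <- sort(match(c("q1", "q2", "q3"), ord))
  expect_equal(diff(range(pos_p)), 2)
  expect_equal(diff(range(pos_q)), 2)
  # zero-variance columns are excluded with a warning
  expect_warning(feature_correlation_clustering(cbind(blocks, k = 1)),
                 "zero-variance")
})

test_that("feature extractors are pure functions", {
  set.seed(15)
  tex <- synth_texture(48, 1)
  expect_identical(contrast_energy_features(tex), contrast_energy_features(tex))
  expect_identical(texture_shape_features(tex), texture_shape_features(tex))
})

test_that("an injected external saliency callable fills the plugin column", {
  uniform <- array(0.5, dim = c(64, 64, 3))
  s <- saliency_features(uniform, c(32, 32))
  expect_true(is.na(s["sal_external"]))
  s2 <- saliency_features(uniform, c(32, 32),
                          external = function(frame, xy) mean(frame) + xy[1])
  expect_equal(unname(s2["sal_external"]), 32.5)
})
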
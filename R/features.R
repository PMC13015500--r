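# Foveal fixation-patch extraction and the per-fixation visual feature
# battery: luminance/color statistics, contrast and spectral energy,
# amplitude-spectrum slope, texture and shape descriptors, center-surround
# saliency, optical flow, and semantic novelty from pluggable patch
# embeddings.
#
# Conventions fixed across the module: images are numeric arrays in [0, 1],
# indexed [row (y), column (x)(, channel)]; "grayscale" means the CIE L*
# channel rescaled to [0, 1]; sRGB -> L*a*b* uses the D65 white point.

#' Screen geometry and pixels per degree
#'
#' @param width_px,height_px screen resolution in pixels
#' @param width_cm,height_cm physical screen size in cm
#' @param viewing_distance_cm eye-to-screen distance in cm
#' @return list of class \code{screen_geometry}
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            viewing_distance_cm) {
  stopifnot(width_px > 0, height_px > 0, width_cm > 0, height_cm > 0,
            viewing_distance_cm > 0)
  structure(list(width_px = width_px, height_px = height_px,
                 width_cm = width_cm, height_cm = height_cm,
                 viewing_distance_cm = viewing_distance_cm),
            class = "screen_geometry")
}

#' @describeIn screen_geometry pixels per degree of visual angle:
#'   2 d tan(0.5 deg) pixels-per-cm, averaged over the two axes.
#' @param geom a \code{screen_geometry}
#' @export
pixels_per_degree <- function(geom) {
  per_cm <- mean(c(geom$width_px / geom$width_cm,
                   geom$height_px / geom$height_cm))
  2 * geom$viewing_distance_cm * tan(pi / 360) * per_cm
}

#' Extract a 5-degree foveal fixation patch
#'
#' Crops a square patch of side \code{round(fov_deg * ppd)} pixels centered
#' on the gaze position and resamples it to \code{out_res}. Off-screen pixels
#' are filled with mid-gray (0.5); the patch is flagged invalid when the gaze
#' is off screen or more than 20\% of the patch had to be filled.
#'
#' @param frame numeric [0,1] array, H x W (grayscale) or H x W x 3 (RGB)
#' @param gaze_xy gaze position in pixels, c(x, y)
#' @param geom a \code{\link{screen_geometry}}
#' @param out_res output resolution (pixels per side)
#' @param fov_deg patch field of view, degrees
#' @return list of class \code{fixation_patch}: \code{pixels} (out_res
#'   square), \code{fov_deg}, \code{valid}, \code{fill_fraction}
#' @export
extract_patch <- function(frame, gaze_xy, geom, out_res = 100,
                          fov_deg = 5) {
  ppd <- pixels_per_degree(geom)
  side <- max(2L, round(fov_deg * ppd))
  H <- dim(frame)[1]; W <- dim(frame)[2]
  nch <- if (length(dim(frame)) == 3) dim(frame)[3] else 1L
  on_screen <- gaze_xy[1] >= 1 && gaze_xy[1] <= W &&
    gaze_xy[2] >= 1 && gaze_xy[2] <= H
  cx <- round(gaze_xy[1]); cy <- round(gaze_xy[2])
  half <- (side - 1) / 2
  rows <- round(cy - half) + 0:(side - 1)
  cols <- round(cx - half) + 0:(side - 1)
  inside_r <- rows >= 1 & rows <= H
  inside_c <- cols >= 1 & cols <= W
  crop <- array(0.5, dim = c(side, side, nch))
  fr <- if (nch == 1) array(frame, dim = c(H, W, 1)) else frame
  crop[inside_r, inside_c, ] <- fr[rows[inside_r], cols[inside_c], ,
                                   drop = FALSE]
  fill <- 1 - mean(inside_r) * mean(inside_c)
  out <- array(0, dim = c(out_res, out_res, nch))
  for (ch in seq_len(nch))
    out[, , ch] <- resize_bilinear(crop[, , ch], out_res)
  if (nch == 1) out <- out[, , 1]
  structure(list(pixels = out, fov_deg = fov_deg,
                 valid = on_screen && fill <= 0.20, fill_fraction = fill),
            class = "fixation_patch")
}

# separable bilinear resize of a matrix to out x out
resize_bilinear <- function(m, out) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (n1 == out && n2 == out) return(m)
  EBImage::resize(m, w = out, h = out)
}

# separable cubic-spline resize (used for the 224 x 224 encoder input)
resize_cubic <- function(m, out) {
  n1 <- nrow(m); n2 <- ncol(m)
  xo1 <- seq(1, n1, length.out = out)
  xo2 <- seq(1, n2, length.out = out)
  tmp <- apply(m, 2, function(col)
    stats::spline(seq_len(n1), col, xout = xo1, method = "natural")$y)
  t(apply(tmp, 1, function(row)
    stats::spline(seq_len(n2), row, xout = xo2, method = "natural")$y))
}

# ---- color helpers -----------------------------------------------------------

# H x W x 3 [0,1] array -> N x 3 Lab matrix (D65)
patch_lab <- function(rgb) {
  px <- cbind(as.numeric(rgb[, , 1]), as.numeric(rgb[, , 2]),
              as.numeric(rgb[, , 3]))
  grDevices::convertColor(px, from = "sRGB", to = "Lab")
}

# grayscale = L* / 100
patch_gray <- function(patch) {
  px <- if (inherits(patch, "fixation_patch")) patch$pixels else patch
  if (length(dim(px)) == 3) {
    lab <- patch_lab(px)
    matrix(lab[, 1] / 100, dim(px)[1], dim(px)[2])
  } else {
    px
  }
}

#' Luminance and color features of an RGB patch
#'
#' CIE L*a*b* (D65): mean L*, population skewness and excess kurtosis of L*
#' (0 for constant patches), mean a*, mean b*. HSV: mean saturation, and hue
#' diversity as the Shannon entropy (bits) of a 16-bin hue histogram over
#' pixels with saturation > 0.1 (0 when no pixel qualifies).
#'
#' @param patch a \code{fixation_patch} or H x W x 3 array in [0, 1]
#' @return named numeric vector of 7 values
#' @export
luminance_color_features <- function(patch) {
  px <- if (inherits(patch, "fixation_patch")) patch$pixels else patch
  if (length(dim(px)) != 3) stop("luminance/color features need an RGB patch")
  lab <- patch_lab(px)
  ms <- moment_stats(lab[, 1])
  hsv <- grDevices::rgb2hsv(rbind(as.numeric(px[, , 1]),
                                  as.numeric(px[, , 2]),
                                  as.numeric(px[, , 3])), maxColorValue = 1)
  sat <- hsv[2, ]; hue <- hsv[1, ]
  sel <- sat > 0.1
  hue_div <- if (any(sel)) {
    cnt <- tabulate(pmin(floor(hue[sel] * 16) + 1L, 16L), 16L)
    shannon_entropy(cnt)
  } else 0
  c(luminance = mean(lab[, 1]), luminance_skew = unname(ms["skew"]),
    luminance_kurtosis = unname(ms["kurtosis"]),
    a_mean = mean(lab[, 2]), b_mean = mean(lab[, 3]),
    saturation = mean(sat), hue_diversity = hue_div)
}

# ---- contrast / energy -------------------------------------------------------

# d/dx differentiates along columns (x); kernels stored column-major
sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobel_y <- t(sobel_x)
scharr_x <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, 3)
scharr_y <- t(scharr_x)

# 2-D convolution with replicated borders (small kernels)
conv2_rep <- function(m, k) {
  kh <- (nrow(k) - 1) %/% 2
  kw <- (ncol(k) - 1) %/% 2
  pad <- m[c(rep(1, kh), seq_len(nrow(m)), rep(nrow(m), kh)),
           c(rep(1, kw), seq_len(ncol(m)), rep(ncol(m), kw))]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(k)))
    for (j in seq_len(ncol(k)))
      if (k[i, j] != 0)
        out <- out + k[i, j] *
          pad[(i - 1) + seq_len(nrow(m)), (j - 1) + seq_len(ncol(m))]
  out
}

#' Contrast and energy features of a patch
#'
#' On the grayscale (L*/100) image: Michelson contrast (max-min)/(max+min);
#' RMS contrast (SD of intensity); sharpness (mean gradient magnitude,
#' central differences); vertical and horizontal energy (mean squared Sobel
#' x / y responses; vertical energy responds to vertical edges); orientation
#' bias (V-H)/(V+H); global entropy of a 32-bin intensity histogram; mean
#' local entropy with a 7 x 7 kernel (16 intensity levels); and HOG energy
#' (L2 norm of a 4 x 4-cell, 9-orientation-bin gradient histogram descriptor,
#' normalized by pixel count). Degenerate constant patches return 0 for
#' Michelson and orientation bias by convention.
#'
#' @param patch a \code{fixation_patch}, grayscale matrix, or RGB array
#' @return named numeric vector of 9 values
#' @export
contrast_energy_features <- function(patch) {
  g <- patch_gray(patch)
  mx <- max(g); mn <- min(g)
  michelson <- if (mx + mn > 0) (mx - mn) / (mx + mn) else 0
  rms <- stats::sd(as.numeric(g))
  gx <- conv2_rep(g, matrix(c(-0.5, 0, 0.5), 1, 3))
  gy <- conv2_rep(g, matrix(c(-0.5, 0, 0.5), 3, 1))
  sharp <- mean(sqrt(gx^2 + gy^2))
  ve <- mean(conv2_rep(g, sobel_x)^2)
  he <- mean(conv2_rep(g, sobel_y)^2)
  obias <- if (ve + he > 0) (ve - he) / (ve + he) else 0
  cnt <- tabulate(pmin(floor(as.numeric(g) * 32) + 1L, 32L), 32L)
  gent <- shannon_entropy(cnt)
  lent <- local_entropy_mean(g, k = 7L, levels = 16L)
  hog <- hog_energy(gx, gy)
  c(michelson = michelson, rms_contrast = rms, sharpness = sharp,
    vertical_energy = ve, horizontal_energy = he, orientation_bias = obias,
    global_entropy = gent, local_entropy = lent, hog_energy = hog)
}

# mean Shannon entropy of k x k neighborhoods after quantizing to `levels`
local_entropy_mean <- function(g, k = 7L, levels = 16L) {
  q <- pmin(floor(g * levels) + 1L, levels)
  box <- matrix(1, k, k)
  counts <- lapply(seq_len(levels), function(l) {
    ind <- matrix(as.numeric(q == l), nrow(g), ncol(g))
    cc <- EBImage::filter2(ind, box, boundary = 0)
    pmax(cc, 0)
  })
  tot <- Reduce(`+`, counts)
  tot[tot < 1e-9] <- 1
  H <- 0
  for (cc in counts) {
    p <- cc / tot
    H <- H - ifelse(p > 1e-12, p * log2(p), 0)
  }
  mean(H)
}

# norm of a coarse HOG descriptor (4 x 4 cells, 9 unsigned orientation bins)
hog_energy <- function(gx, gy, cells = 4L, bins = 9L) {
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / pi * bins) + 1L, bins)
  ci <- pmin(floor((row(gx) - 1) / nrow(gx) * cells) + 1L, cells)
  cj <- pmin(floor((col(gx) - 1) / ncol(gx) * cells) + 1L, cells)
  idx <- (ci - 1L) * cells * bins + (cj - 1L) * bins + bin
  desc <- vapply(seq_len(cells * cells * bins), function(i)
    sum(mag[idx == i]), numeric(1))
  sqrt(sum(desc^2)) / length(gx)
}

#' Amplitude-spectrum slope of a patch
#'
#' 2-D Fourier magnitude of the grayscale (L*) image, radially averaged into
#' 8 logarithmically spaced frequency bins between 0.1 and 10 cycles/degree
#' (9 geometric edges; a coefficient with radial frequency f belongs to bin i
#' when edge_i <= f < edge_{i+1}; DC excluded), followed by an ordinary
#' least-squares fit of log10 mean magnitude against log10 bin center
#' (geometric mean of the edges). Returns the negative of the fitted slope,
#' so a 1/f^alpha amplitude spectrum yields alpha. Empty bins are dropped
#' with a warning; fewer than 3 nonempty bins is an error.
#'
#' @param patch a \code{fixation_patch}, grayscale matrix, or RGB array
#' @param ppd pixels per degree of the patch
#' @param f_range frequency range in cycles/degree
#' @param n_bins number of log-spaced bins
#' @return spectrum slope (dimensionless exponent)
#' @export
spectrum_slope <- function(patch, ppd, f_range = c(0.1, 10), n_bins = 8) {
  g <- patch_gray(patch)
  if (nrow(g) < 16 || ncol(g) < 16) stop("patch too small (need >= 16 x 16)")
  stopifnot(ppd > 0)
  F <- stats::fft(g - mean(g))
  n1 <- nrow(g); n2 <- ncol(g)
  f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
  fr <- sqrt(outer(f1^2, f2^2, "+")) * ppd  # cycles/degree
  mag <- Mod(F)
  edges <- exp(seq(log(f_range[1]), log(f_range[2]),
                   length.out = n_bins + 1))
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  mean_mag <- vapply(seq_len(n_bins), function(i) {
    sel <- fr >= edges[i] & fr < edges[i + 1] & fr > 0
    if (!any(sel)) NA_real_ else mean(mag[sel])
  }, numeric(1))
  ok <- !is.na(mean_mag) & mean_mag > 0
  if (sum(ok) < n_bins)
    warning(sum(!ok), " empty frequency bin(s) dropped")
  if (sum(ok) < 3) stop("fewer than 3 nonempty frequency bins")
  fit <- stats::lm(log10(mean_mag[ok]) ~ log10(centers[ok]))
  -unname(stats::coef(fit)[2])
}

# ---- texture / shape ---------------------------------------------------------

#' Texture and shape features of a patch
#'
#' On the grayscale image: local-binary-pattern histogram energy (8-neighbor
#' LBP, sum of squared normalized histogram); Scharr and Sobel edge density
#' (fraction of pixels whose gradient magnitude exceeds the Otsu threshold of
#' the magnitude map); Hough line and circle counts at fixed parameters
#' (5-degree angular resolution, 1-px rho; radii at 10/15/20/25\% of the
#' side; peaks above half the accumulator maximum after 3 x 3 non-maximum
#' suppression); gray-level co-occurrence (GLCM, offset 1 px, 4 directions
#' averaged, 32 levels, symmetric) contrast, homogeneity, correlation, and
#' angular second moment; and blob statistics (threshold at the mean gray
#' value): blob count, mean eccentricity, mean solidity. A constant patch has
#' GLCM contrast 0, homogeneity 1, ASM 1, correlation 0 (zero-variance
#' convention), and 0 blobs.
#'
#' @param patch a \code{fixation_patch}, grayscale matrix, or RGB array
#' @return named numeric vector of 12 values
#' @export
texture_shape_features <- function(patch) {
  g <- patch_gray(patch)
  lbp <- lbp_energy(g)
  sch <- edge_density(g, scharr_x, scharr_y)
  sob <- edge_density(g, sobel_x, sobel_y)
  hl <- hough_line_count(g)
  hc <- hough_circle_count(g)
  gl <- glcm_features(g, levels = 32L)
  bl <- blob_features(g)
  c(lbp_energy = lbp, scharr_density = sch, sobel_density = sob,
    hough_lines = hl, hough_circles = hc,
    glcm_contrast = unname(gl["contrast"]),
    glcm_homogeneity = unname(gl["homogeneity"]),
    glcm_correlation = unname(gl["correlation"]),
    glcm_asm = unname(gl["asm"]),
    blob_count = unname(bl["count"]),
    blob_eccentricity = unname(bl["eccentricity"]),
    blob_solidity = unname(bl["solidity"]))
}

lbp_energy <- function(g) {
  n1 <- nrow(g); n2 <- ncol(g)
  if (n1 < 3 || n2 < 3) return(1)
  c0 <- g[2:(n1 - 1), 2:(n2 - 1)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, n1 - 2, n2 - 2)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    nb <- g[2:(n1 - 1) + o[1], 2:(n2 - 1) + o[2]]
    code <- code + as.integer(nb >= c0) * 2L^(k - 1L)
  }
  h <- tabulate(code + 1L, 256L)
  p <- h / sum(h)
  sum(p^2)
}

edge_density <- function(g, kx, ky) {
  mag <- sqrt(conv2_rep(g, kx)^2 + conv2_rep(g, ky)^2)
  mx <- max(mag)
  if (mx <= 0) return(0)
  thr <- EBImage::otsu(mag / mx, range = c(0, 1)) * mx
  mean(mag > thr)
}

edge_map <- function(g) {
  mag <- sqrt(conv2_rep(g, sobel_x)^2 + conv2_rep(g, sobel_y)^2)
  mx <- max(mag)
  if (mx <= 0) return(matrix(FALSE, nrow(g), ncol(g)))
  mag > EBImage::otsu(mag / mx, range = c(0, 1)) * mx
}

# count 3x3-NMS accumulator peaks above frac * max and an absolute floor
count_peaks <- function(acc, frac = 0.5, floor_votes = 2) {
  mx <- max(acc)
  if (mx < floor_votes) return(0L)
  thr <- max(frac * mx, floor_votes)
  n1 <- nrow(acc); n2 <- ncol(acc)
  cnt <- 0L
  for (i in seq_len(n1))
    for (j in seq_len(n2)) {
      v <- acc[i, j]
      if (v < thr) next
      nb <- acc[max(1, i - 1):min(n1, i + 1), max(1, j - 1):min(n2, j + 1)]
      if (v >= max(nb)) cnt <- cnt + 1L
    }
  cnt
}

hough_line_count <- function(g, theta_step_deg = 5, rho_res = 1) {
  ed <- which(edge_map(g), arr.ind = TRUE)
  if (nrow(ed) < 5) return(0L)
  th <- seq(0, 175, by = theta_step_deg) * pi / 180
  diag_len <- ceiling(sqrt(nrow(g)^2 + ncol(g)^2))
  rho <- ed[, 2] %o% cos(th) + ed[, 1] %o% sin(th)
  ri <- round(rho / rho_res) + diag_len + 1L
  acc <- matrix(0L, 2L * diag_len + 2L, length(th))
  for (j in seq_along(th)) {
    tab <- tabulate(ri[, j], nbins = nrow(acc))
    acc[, j] <- tab
  }
  count_peaks(acc, frac = 0.5, floor_votes = max(5, 0.25 * min(dim(g))))
}

hough_circle_count <- function(g, radii = NULL, n_angles = 36) {
  if (is.null(radii))
    radii <- unique(pmax(3, round(min(dim(g)) * c(0.10, 0.15, 0.20, 0.25))))
  ed <- which(edge_map(g), arr.ind = TRUE)
  if (nrow(ed) < 8) return(0L)
  ang <- seq(0, 2 * pi, length.out = n_angles + 1)[-1]
  total <- 0L
  for (r in radii) {
    acc <- matrix(0L, nrow(g), ncol(g))
    for (a in ang) {
      ci <- round(ed[, 1] + r * sin(a))
      cj <- round(ed[, 2] + r * cos(a))
      ok <- ci >= 1 & ci <= nrow(g) & cj >= 1 & cj <= ncol(g)
      if (!any(ok)) next
      ii <- cbind(ci[ok], cj[ok])
      for (k in seq_len(nrow(ii)))
        acc[ii[k, 1], ii[k, 2]] <- acc[ii[k, 1], ii[k, 2]] + 1L
    }
    total <- total + count_peaks(acc, frac = 0.5,
                                 floor_votes = 0.6 * n_angles)
  }
  total
}

#' Gray-level co-occurrence features
#'
#' Symmetric GLCM at offset 1 px in 4 directions (0, 45, 90, 135 degrees),
#' averaged. Intensities are quantized into \code{levels} equal bins over
#' [0, 1].
#'
#' @param g grayscale matrix in [0, 1]
#' @param levels number of gray levels
#' @return named vector: contrast, homogeneity, correlation, asm
#' @export
glcm_features <- function(g, levels = 32L) {
  q <- pmin(floor(g * levels) + 1L, levels)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  feats <- matrix(0, length(offs), 4)
  ii <- seq_len(levels)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    r1 <- max(1, 1 - o[1]):min(nrow(g), nrow(g) - o[1])
    c1 <- max(1, 1 - o[2]):min(ncol(g), ncol(g) - o[2])
    a <- q[r1, c1]
    b <- q[r1 + o[1], c1 + o[2]]
    P <- matrix(0, levels, levels)
    tab <- table(factor(a, levels = ii), factor(b, levels = ii))
    P <- P + tab + t(tab)
    P <- P / sum(P)
    mu_i <- sum(ii * rowSums(P)); mu_j <- sum(ii * colSums(P))
    sd_i <- sqrt(sum((ii - mu_i)^2 * rowSums(P)))
    sd_j <- sqrt(sum((ii - mu_j)^2 * colSums(P)))
    D <- outer(ii, ii, "-")
    contrast <- sum(P * D^2)
    homog <- sum(P / (1 + abs(D)))
    corr <- if (sd_i > 0 && sd_j > 0)
      sum(P * outer(ii - mu_i, ii - mu_j)) / (sd_i * sd_j) else 0
    asm <- sum(P^2)
    feats[k, ] <- c(contrast, homog, corr, asm)
  }
  stats::setNames(colMeans(feats),
                  c("contrast", "homogeneity", "correlation", "asm"))
}

# blob statistics after thresholding at the mean gray value
blob_features <- function(g) {
  bw <- g > mean(g)
  if (!any(bw)) return(c(count = 0, eccentricity = 0, solidity = 0))
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(g), ncol(g)))
  nl <- max(lab)
  ecc <- sol <- numeric(nl)
  for (k in seq_len(nl)) {
    pix <- which(lab == k, arr.ind = TRUE)
    n <- nrow(pix)
    if (n < 3) { ecc[k] <- 0; sol[k] <- 1; next }
    cc <- scale(pix, scale = FALSE)
    S <- crossprod(cc) / n + diag(1 / 12, 2)  # pixel-extent regularization
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    ecc[k] <- sqrt(max(0, 1 - ev[2] / ev[1]))
    hull <- grDevices::chull(pix[, 2], pix[, 1])
    hx <- pix[hull, 2]; hy <- pix[hull, 1]
    ha <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    # lattice-point count of the hull polygon (Pick): A + P/2 + 1
    sol[k] <- min(1, n / max(ha + per / 2 + 1, 1))
  }
  c(count = nl, eccentricity = mean(ecc), solidity = mean(sol))
}

# ---- center-surround saliency ------------------------------------------------

gabor_kernel <- function(theta, size = 11, lambda = 6, sigma = 3,
                         gamma = 0.8) {
  h <- (size - 1) / 2
  xy <- expand.grid(x = -h:h, y = -h:h)
  xp <- xy$x * cos(theta) + xy$y * sin(theta)
  yp <- -xy$x * sin(theta) + xy$y * cos(theta)
  k <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / lambda)
  k <- k - mean(k)
  matrix(k, size, size)
}

# bilinear sample of matrix m at (x, y) in its own pixel coordinates
sample_at <- function(m, x, y) {
  x <- min(max(x, 1), ncol(m)); y <- min(max(y, 1), nrow(m))
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, ncol(m)); y1 <- min(y0 + 1, nrow(m))
  fx <- x - x0; fy <- y - y0
  (1 - fy) * ((1 - fx) * m[y0, x0] + fx * m[y0, x1]) +
    fy * ((1 - fx) * m[y1, x0] + fx * m[y1, x1])
}

#' Center-surround saliency features at the fixated location
#'
#' An Itti-Koch-style architecture: dyadic Gaussian pyramids of intensity
#' (r+g+b)/3, red-green opponency (R - G) and blue-yellow opponency (B - Y),
#' plus Gabor orientation energy at 4 orientations. Center-surround values
#' are absolute differences between pyramid levels c in \{2,3,4\} and
#' s = c + delta, delta in \{3,4\} (6 scale pairs), each sampled at the gaze
#' location. Returns 28 values: 6 intensity, 6 RG, 6 BY, 4 per-orientation
#' summaries (mean over the 6 scale pairs) and 6 per-scale-pair summaries
#' (mean over the 4 orientations).
#'
#' An external saliency model (for example a pretrained gaze-prediction
#' network) can be injected as a callable \code{function(frame, gaze_xy)}
#' returning one number; without one the extra column is reported missing
#' (NA) and the pipeline continues.
#'
#' @param frame H x W x 3 RGB array in [0, 1] (grayscale frames give zero
#'   color opponency)
#' @param gaze_xy fixated location in pixels, c(x, y)
#' @param external optional external saliency callable (see above)
#' @return named numeric vector of 28 values, plus \code{sal_external}
#'   (NA when no callable is given)
#' @export
saliency_features <- function(frame, gaze_xy, external = NULL) {
  if (length(dim(frame)) == 2)
    frame <- array(rep(frame, 3), dim = c(dim(frame), 3))
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  I <- (r + g + b) / 3
  RG <- r - g
  BY <- b - (r + g) / 2
  n_levels <- 8
  pyr <- function(m) {
    out <- vector("list", n_levels)
    out[[1]] <- m
    for (k in 2:n_levels) {
      prev <- out[[k - 1]]
      w <- max(4, ncol(prev) %/% 2); h <- max(4, nrow(prev) %/% 2)
      sm <- if (min(dim(prev)) >= 9) EBImage::gblur(prev, sigma = 1) else prev
      out[[k]] <- EBImage::resize(sm, w = w, h = h)
    }
    out
  }
  pI <- pyr(I); pRG <- pyr(RG); pBY <- pyr(BY)
  thetas <- (0:3) * pi / 4
  pO <- lapply(thetas, function(th) {
    k <- gabor_kernel(th)
    lapply(pI, function(lvl)
      if (min(dim(lvl)) >= 11) abs(EBImage::filter2(lvl, k, boundary = 0))
      else matrix(0, nrow(lvl), ncol(lvl)))
  })
  pairs <- rbind(c(2, 5), c(2, 6), c(3, 6), c(3, 7), c(4, 7), c(4, 8))
  cs_at <- function(pyrlist, c_lvl, s_lvl) {
    sc_c <- 2^(c_lvl - 1); sc_s <- 2^(s_lvl - 1)
    vc <- sample_at(pyrlist[[c_lvl]],
                    (gaze_xy[1] - 1) * ncol(pyrlist[[c_lvl]]) /
                      ncol(pyrlist[[1]]) + 1,
                    (gaze_xy[2] - 1) * nrow(pyrlist[[c_lvl]]) /
                      nrow(pyrlist[[1]]) + 1)
    vs <- sample_at(pyrlist[[s_lvl]],
                    (gaze_xy[1] - 1) * ncol(pyrlist[[s_lvl]]) /
                      ncol(pyrlist[[1]]) + 1,
                    (gaze_xy[2] - 1) * nrow(pyrlist[[s_lvl]]) /
                      nrow(pyrlist[[1]]) + 1)
    abs(vc - vs)
  }
  int_cs <- vapply(seq_len(6), function(i)
    cs_at(pI, pairs[i, 1], pairs[i, 2]), numeric(1))
  rg_cs <- vapply(seq_len(6), function(i)
    cs_at(pRG, pairs[i, 1], pairs[i, 2]), numeric(1))
  by_cs <- vapply(seq_len(6), function(i)
    cs_at(pBY, pairs[i, 1], pairs[i, 2]), numeric(1))
  ori <- sapply(pO, function(pyrlist)
    vapply(seq_len(6), function(i)
      cs_at(pyrlist, pairs[i, 1], pairs[i, 2]), numeric(1)))
  # ori: 6 pairs x 4 orientations
  out <- c(int_cs, rg_cs, by_cs, colMeans(ori), rowMeans(ori))
  names(out) <- c(paste0("sal_int", 1:6), paste0("sal_rg", 1:6),
                  paste0("sal_by", 1:6), paste0("sal_ori_th", 1:4),
                  paste0("sal_ori_sc", 1:6))
  ext <- if (is.null(external)) NA_real_ else as.numeric(external(frame, gaze_xy))
  c(out, sal_external = ext)
}

# ---- optical flow ------------------------------------------------------------

#' Mean optical-flow magnitude preceding a saccade
#'
#' Averages the flow magnitude over the (10x-downsampled) patch region and
#' the frames whose times fall within [onset - 250 ms, onset - 50 ms]. For
#' still images pass \code{flow = NULL}: the feature is 0. A window entirely
#' before the recording start returns NA (flagged missing).
#'
#' @param flow frames x H x W x 2 array of flow fields (downsampled), or NULL
#' @param frame_times frame times in seconds
#' @param patch_box full-resolution patch box c(x0, x1, y0, y1) in pixels
#' @param saccade_onset saccade onset time, seconds
#' @param downsample spatial downsampling factor of the flow fields
#' @param window flow window relative to saccade onset, seconds
#' @return mean flow magnitude (pixels/frame at full resolution), 0, or NA
#' @export
optical_flow_feature <- function(flow, frame_times, patch_box, saccade_onset,
                                 downsample = 10,
                                 window = c(-0.250, -0.050)) {
  if (is.null(flow)) return(0)
  t0 <- saccade_onset + window[1]; t1 <- saccade_onset + window[2]
  if (t1 < frame_times[1]) return(NA_real_)
  sel <- which(frame_times >= t0 & frame_times <= t1)
  if (!length(sel)) return(NA_real_)
  cs <- pmax(1, round(patch_box[1] / downsample)):
    min(dim(flow)[3], max(1, round(patch_box[2] / downsample)))
  rs <- pmax(1, round(patch_box[3] / downsample)):
    min(dim(flow)[2], max(1, round(patch_box[4] / downsample)))
  mags <- vapply(sel, function(f) {
    u <- flow[f, rs, cs, 1]; v <- flow[f, rs, cs, 2]
    mean(sqrt(u^2 + v^2))
  }, numeric(1))
  mean(mags)
}

# ---- embeddings and novelty --------------------------------------------------

#' The default toy patch encoder
#'
#' A deterministic random-projection encoder: the input patch (after the
#' standard resize to 224 x 224) is reduced to 32 x 32 by block averaging,
#' centered, projected through a fixed-seed Gaussian matrix to
#' \code{dim} dimensions, and passed through tanh. It preserves
#' patch-similarity structure (similar patches map to nearby embeddings)
#' without any pretrained weights. A pretrained encoder (e.g. a
#' contrastive-learning network) can be supplied anywhere an encoder is
#' accepted: any list with fields \code{id}, \code{dim}, and \code{fun}
#' (a function from a 224 x 224 matrix to a numeric vector) works.
#'
#' @param dim embedding dimension
#' @param seed internal projection seed (fixed default; change only to get a
#'   different encoder)
#' @return list of class \code{patch_encoder}
#' @export
toy_encoder <- function(dim = 128L, seed = 20240613L) {
  old <- .Random.seed_save()
  set.seed(seed)
  W <- matrix(stats::rnorm(dim * 1024), dim, 1024) / sqrt(1024)
  bvec <- stats::rnorm(dim, sd = 0.1)
  .Random.seed_restore(old)
  fun <- function(m224) {
    # 224 = 32 * 7: exact block means
    blk <- matrix(0, 32, 32)
    for (i in 1:32)
      for (j in 1:32)
        blk[i, j] <- mean(m224[(i - 1) * 7 + 1:7, (j - 1) * 7 + 1:7])
    v <- as.numeric(blk)
    v <- v - mean(v)
    tanh(as.numeric(W %*% v) + bvec)
  }
  structure(list(id = sprintf("toy-rp-%d-%d", dim, seed), dim = dim,
                 fun = fun), class = "patch_encoder")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Embed a fixation patch
#'
#' The patch is converted to grayscale if needed, resized to 224 x 224 by
#' cubic spline interpolation, and passed through the encoder. Deterministic
#' for a fixed encoder.
#'
#' @param patch a \code{fixation_patch}, matrix, or RGB array
#' @param encoder a \code{\link{toy_encoder}}-style encoder
#' @return list of class \code{patch_embedding}: \code{vector},
#'   \code{encoder_id}
#' @export
embed_patch <- function(patch, encoder = toy_encoder()) {
  g <- patch_gray(patch)
  g <- matrix(as.numeric(g), nrow(g), ncol(g))
  m224 <- if (all(dim(g) == c(224, 224))) g else resize_cubic(g, 224)
  v <- encoder$fun(m224)
  if (any(!is.finite(v))) stop("encoder returned non-finite embedding")
  structure(list(vector = v, encoder_id = encoder$id),
            class = "patch_embedding")
}

#' Semantic novelty: cosine distance between consecutive patch embeddings
#'
#' 1 - cos(e_prev, e_curr), in [0, 2]: 0 for identical directions, 1 for
#' orthogonal, 2 for opposite embeddings. High values mean semantically
#' unrelated content across the saccade.
#'
#' @param e_prev,e_curr \code{patch_embedding}s from the same encoder
#' @return numeric in [0, 2]
#' @export
novelty <- function(e_prev, e_curr) {
  v1 <- if (inherits(e_prev, "patch_embedding")) e_prev$vector else e_prev
  v2 <- if (inherits(e_curr, "patch_embedding")) e_curr$vector else e_curr
  if (inherits(e_prev, "patch_embedding") &&
      inherits(e_curr, "patch_embedding") &&
      !identical(e_prev$encoder_id, e_curr$encoder_id))
    stop("embeddings come from different encoders")
  if (length(v1) != length(v2)) stop("embedding dimensions differ")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm embedding")
  1 - sum(v1 * v2) / (n1 * n2)
}

#' Hierarchically clustered feature correlation matrix
#'
#' Pearson correlations across feature columns, reordered by average-linkage
#' hierarchical clustering on the distance 1 - |r|. Zero-variance columns are
#' excluded with a warning.
#'
#' @param table data.frame or matrix of per-event feature values
#' @return list: \code{R} (reordered correlation matrix), \code{order}
#'   (column names in cluster order), \code{hclust}
#' @export
feature_correlation_clustering <- function(table) {
  M <- as.matrix(table)
  if (ncol(M) < 2 || nrow(M) < 3)
    stop("need at least 2 features and 3 rows")
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning("excluding zero-variance column(s): ",
            paste(colnames(M)[drop], collapse = ", "))
    M <- M[, !drop, drop = FALSE]
  }
  R <- stats::cor(M, use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - abs(R)), method = "average")
  ord <- hc$order
  list(R = R[ord, ord], order = colnames(M)[ord], hclust = hc)
}

#' Full per-patch feature battery
#'
#' Convenience wrapper combining \code{\link{luminance_color_features}},
#' \code{\link{contrast_energy_features}}, \code{\link{spectrum_slope}}, and
#' \code{\link{texture_shape_features}} into one named vector (29 values).
#'
#' @param patch RGB \code{fixation_patch} or array
#' @param ppd pixels per degree (for the spectrum slope)
#' @return named numeric vector
#' @export
patch_features <- function(patch, ppd) {
  slope <- tryCatch(
    suppressWarnings(spectrum_slope(patch, ppd)),
    error = function(e) NA_real_)
  c(luminance_color_features(patch), contrast_energy_features(patch),
    spectrum_slope = slope, texture_shape_features(patch))
}
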
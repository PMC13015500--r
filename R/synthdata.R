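# Synthetic gaze / stimulus / neural generators with known ground truth.
#
# The generators emulate the structure of free-viewing recordings: saccade and
# fixation event trains with gamma-distributed fixation durations, a
# main-sequence-like relation between saccade amplitude and duration, feature
# values correlated across saccades (notably amplitude vs novelty), and neural
# signals built by convolving known impulse responses (TRFs) with event and
# feature regressors, plus 1/f noise (scalp mode) or an amplitude-modulated
# 70-150 Hz multi-tone carrier (BHA mode).

#' Configuration for the synthetic free-viewing generators
#'
#' Defaults describe the simulated study conditions used throughout the test
#' suite: 100 Hz neural sampling (the analysis rate), 500 Hz gaze sampling,
#' gamma fixation durations with mean 0.3 s (shape 6, scale 0.05; fixations
#' under 110 ms are rare, ~2.5\%), saccade amplitudes of 1-12 degrees, and an
#' amplitude-novelty correlation of 0.4.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical outputs
#' @param duration_s recording duration in seconds (> 0)
#' @param gaze_fs gaze sampling rate, Hz
#' @param neural_fs neural sampling rate, Hz
#' @param n_channels number of neural channels
#' @param fixation_duration_shape,fixation_duration_scale gamma parameters of
#'   fixation duration (seconds)
#' @param min_fixation_s minimum fixation duration enforced by redrawing
#' @param amplitude_range saccade amplitude range in degrees (length 2)
#' @param amplitude_novelty_rho target Pearson correlation between saccade
#'   amplitude and novelty, in [0, 1)
#' @param noise_sd additive noise SD in signal units (neural); ignored when
#'   \code{snr} is given
#' @param snr optional signal-to-noise ratio (RMS of clean signal over RMS of
#'   noise); overrides \code{noise_sd}
#' @param gaze_noise_deg additive gaze position noise SD, degrees
#' @param blink_rate_hz Poisson rate of low-quality (blink) segments
#' @param mode \code{"scalp-potential"} (TRF signal plus 1/f noise) or
#'   \code{"bha-carrier"} (TRF signal amplitude-modulates a 70-150 Hz carrier)
#' @param n_modulated number of channels carrying a nonzero novelty TRF
#' @return list of class \code{synth_config}
#' @export
synth_config <- function(seed = 1L,
                         duration_s = 300,
                         gaze_fs = 500,
                         neural_fs = 100,
                         n_channels = 20,
                         fixation_duration_shape = 6,
                         fixation_duration_scale = 0.05,
                         min_fixation_s = 0.08,
                         amplitude_range = c(1, 12),
                         amplitude_novelty_rho = 0.4,
                         noise_sd = 1,
                         snr = NULL,
                         gaze_noise_deg = 0.02,
                         blink_rate_hz = 0.05,
                         mode = c("scalp-potential", "bha-carrier"),
                         n_modulated = 5) {
  mode <- match.arg(mode)
  stopifnot(duration_s > 0, gaze_fs > 0, neural_fs > 0, n_channels >= 1,
            amplitude_novelty_rho >= 0, amplitude_novelty_rho < 1,
            length(amplitude_range) == 2, diff(amplitude_range) > 0)
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 gaze_fs = gaze_fs, neural_fs = neural_fs,
                 n_channels = n_channels,
                 fixation_duration_shape = fixation_duration_shape,
                 fixation_duration_scale = fixation_duration_scale,
                 min_fixation_s = min_fixation_s,
                 amplitude_range = amplitude_range,
                 amplitude_novelty_rho = amplitude_novelty_rho,
                 noise_sd = noise_sd, snr = snr,
                 gaze_noise_deg = gaze_noise_deg,
                 blink_rate_hz = blink_rate_hz, mode = mode,
                 n_modulated = min(n_modulated, n_channels)),
            class = "synth_config")
}

# saccade duration from the main-sequence approximation: 2.2 ms/deg + 21 ms
saccade_duration_s <- function(amplitude_deg) 0.0022 * amplitude_deg + 0.021

#' Generate a synthetic gaze recording with ground-truth events
#'
#' Fixation durations are gamma distributed (truncated below
#' \code{min_fixation_s}); saccades follow a raised-cosine (minimum-jerk-like)
#' velocity profile with duration 2.2 ms/deg + 21 ms, giving realistic peak
#' velocities (about 300 deg/s for a 5 degree saccade). Gaze stays within a
#' +-15 degree box by reflecting candidate directions. Low-quality (blink)
#' segments of 100-300 ms are inserted at Poisson times and marked invalid
#' (positions set to NA).
#'
#' @param config a \code{\link{synth_config}}
#' @return list with elements \code{gaze} (a \code{gaze_recording}; see
#'   \code{\link{gaze_recording}}) and \code{truth} (ground-truth list with
#'   the event table, per-event latent scores, and blink windows)
#' @export
generate_gaze <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 1L))
  dur <- config$duration_s
  fs <- config$gaze_fs
  # --- event sequence ---------------------------------------------------
  t_cur <- 0.4
  sacc_on <- sacc_off <- fix_on <- fix_dur <- amp <- dir <- numeric(0)
  repeat {
    a <- config$amplitude_range[1] +
      diff(config$amplitude_range) * stats::qbeta(stats::runif(1), 1.8, 3.5)
    sd_s <- saccade_duration_s(a)
    fd <- stats::rgamma(1, shape = config$fixation_duration_shape,
                        scale = config$fixation_duration_scale)
    while (fd < config$min_fixation_s)
      fd <- stats::rgamma(1, shape = config$fixation_duration_shape,
                          scale = config$fixation_duration_scale)
    if (t_cur + sd_s + fd > dur - 0.3) break
    sacc_on <- c(sacc_on, t_cur)
    sacc_off <- c(sacc_off, t_cur + sd_s)
    fix_on <- c(fix_on, t_cur + sd_s)
    fix_dur <- c(fix_dur, fd)
    amp <- c(amp, a)
    dir <- c(dir, stats::runif(1, 0, 2 * pi))
    t_cur <- t_cur + sd_s + fd
  }
  n_ev <- length(sacc_on)
  if (n_ev < 1)
    stop("duration_s too short to contain a single fixation")
  # --- positions: integrate raised-cosine displacement profiles ---------
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n); y <- numeric(n)
  px <- 0; py <- 0
  pos_x <- numeric(n_ev + 1); pos_y <- numeric(n_ev + 1)
  pos_x[1] <- px; pos_y[1] <- py
  for (k in seq_len(n_ev)) {
    # reflect direction until the landing point stays inside +-15 deg
    dx <- amp[k] * cos(dir[k]); dy <- amp[k] * sin(dir[k])
    tries <- 0
    while ((abs(px + dx) > 15 || abs(py + dy) > 15) && tries < 50) {
      dir[k] <- stats::runif(1, 0, 2 * pi)
      dx <- amp[k] * cos(dir[k]); dy <- amp[k] * sin(dir[k])
      tries <- tries + 1
    }
    seg <- which(t >= sacc_on[k] & t < sacc_off[k])
    if (length(seg)) {
      ph <- (t[seg] - sacc_on[k]) / (sacc_off[k] - sacc_on[k])
      prof <- ph - sin(2 * pi * ph) / (2 * pi)  # raised-cosine velocity
      x[seg] <- px + dx * prof
      y[seg] <- py + dy * prof
    }
    px <- px + dx; py <- py + dy
    pos_x[k + 1] <- px; pos_y[k + 1] <- py
    until <- if (k < n_ev) sacc_on[k + 1] else dur + 1
    seg2 <- which(t >= sacc_off[k] & t < until)
    x[seg2] <- px; y[seg2] <- py
  }
  x[t < sacc_on[1]] <- pos_x[1]; y[t < sacc_on[1]] <- pos_y[1]
  if (config$gaze_noise_deg > 0) {
    x <- x + stats::rnorm(n, sd = config$gaze_noise_deg)
    y <- y + stats::rnorm(n, sd = config$gaze_noise_deg)
  }
  # --- blink (low-quality) windows --------------------------------------
  valid <- rep(TRUE, n)
  n_blinks <- stats::rpois(1, config$blink_rate_hz * dur)
  blink_on <- sort(stats::runif(n_blinks, 0, dur))
  blink_dur <- stats::runif(n_blinks, 0.1, 0.3)
  for (b in seq_len(n_blinks)) {
    idx <- which(t >= blink_on[b] & t <= blink_on[b] + blink_dur[b])
    valid[idx] <- FALSE
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  rec <- gaze_recording(t = t, x = x, y = y, valid = valid, fs = fs)
  events <- data.frame(saccade_onset = sacc_on, saccade_offset = sacc_off,
                       fixation_onset = fix_on, fixation_duration = fix_dur,
                       amplitude = amp, direction = dir)
  truth <- list(events = events,
                blink_on = blink_on, blink_dur = blink_dur,
                positions = cbind(x = pos_x, y = pos_y))
  list(gaze = rec, truth = truth)
}

#' Generate a per-event feature table with a controlled amplitude-novelty
#' correlation
#'
#' Novelty is generated through a Gaussian copula tied to the copula score of
#' the (already drawn) saccade amplitudes, with a Beta(2.2, 2.8) marginal
#' scaled to [0, 2] (cosine-distance range). Low-level features (luminance,
#' spectrum slope, optic flow and their across-saccade differences) are drawn
#' independently of novelty.
#'
#' @param config a \code{\link{synth_config}}
#' @param truth ground truth from \code{\link{generate_gaze}}
#' @return data.frame, one row per saccade: \code{amplitude}, \code{novelty},
#'   \code{luminance}, \code{d_luminance}, \code{spectrum_slope},
#'   \code{d_spectrum_slope}, \code{optic_flow}
#' @export
generate_feature_table <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 2L))
  ev <- truth$events
  n <- nrow(ev)
  rho <- config$amplitude_novelty_rho
  # copula score of the realized amplitudes
  u_amp <- (rank(ev$amplitude, ties.method = "average") - 0.5) / n
  z_amp <- stats::qnorm(u_amp)
  z_nov <- rho * z_amp + sqrt(1 - rho^2) * stats::rnorm(n)
  novelty <- 2 * stats::qbeta(stats::pnorm(z_nov), 2.2, 2.8)
  lum <- stats::rnorm(n, 50, 12)
  slope <- stats::rnorm(n, 1.0, 0.25)
  flow <- abs(stats::rnorm(n, 1, 0.6))
  data.frame(amplitude = ev$amplitude,
             novelty = novelty,
             luminance = lum,
             d_luminance = c(NA, diff(lum)),
             spectrum_slope = slope,
             d_spectrum_slope = c(NA, diff(slope)),
             optic_flow = flow)
}

#' Generate a sequence of fixation-patch pairs with duplicate/redraw labels
#'
#' Each pair is either a near-duplicate (the same 1/f^alpha texture with a
#' small circular jitter and optional pixel noise) or two independent redraws
#' from the same texture family. Textures are synthesized in the frequency
#' domain with amplitude spectrum exactly proportional to f^-alpha and random
#' phases, so the spectrum-slope estimator has a known target.
#'
#' @param config a \code{\link{synth_config}}
#' @param n_pairs number of patch pairs
#' @param side patch side length in pixels
#' @param alpha spectral exponent of the texture family
#' @param p_duplicate probability that a pair is a near-duplicate
#' @param jitter_px circular-shift jitter (pixels) applied to duplicates
#' @param noise_sd pixel noise added to the second member of duplicate pairs
#' @return list with \code{pairs} (list of 2-element lists of matrices in
#'   [0, 1]) and \code{is_duplicate} (logical vector)
#' @export
generate_patch_pair_sequence <- function(config, n_pairs = 100, side = 64,
                                         alpha = 1.0, p_duplicate = 0.5,
                                         jitter_px = 2, noise_sd = 0.01) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 3L))
  is_dup <- stats::runif(n_pairs) < p_duplicate
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- synth_texture(side, alpha)
    if (is_dup[i]) {
      sh <- if (jitter_px > 0) sample(-jitter_px:jitter_px, 2, TRUE) else c(0, 0)
      b <- a[((seq_len(side) - 1 + sh[1]) %% side) + 1,
             ((seq_len(side) - 1 + sh[2]) %% side) + 1]
      if (noise_sd > 0) b <- b + stats::rnorm(side * side, sd = noise_sd)
    } else {
      b <- synth_texture(side, alpha)
    }
    pairs[[i]] <- list(pmin(pmax(a, 0), 1), pmin(pmax(b, 0), 1))
  }
  list(pairs = pairs, is_duplicate = is_dup)
}

#' Synthesize a single 1/f^alpha texture patch
#'
#' Amplitude spectrum |F(f)| proportional to f^-alpha with uniform random
#' phases (Hermitian-symmetrized through taking the real part); rescaled to
#' mean 0.5 and SD 0.15, values in [0, 1] after clipping.
#'
#' @param side side length in pixels
#' @param alpha spectral exponent (0 = white noise)
#' @return side x side numeric matrix
#' @export
synth_texture <- function(side, alpha) {
  fx <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- fr
  amp[1, 1] <- Inf
  amp <- amp^(-alpha)
  amp[1, 1] <- 0
  ph <- matrix(stats::runif(side * side, 0, 2 * pi), side, side)
  F <- matrix(complex(modulus = amp, argument = ph), side, side)
  img <- Re(stats::fft(F, inverse = TRUE)) / (side * side)
  s <- stats::sd(img)
  if (s > 0) img <- (img - mean(img)) / s
  pmin(pmax(0.5 + 0.15 * img, 0), 1)
}

#' Default ground-truth TRF shapes used by the neural generator
#'
#' Deterministic per (band, channel): damped-oscillation waveforms whose
#' polarity, latency, and frequency vary smoothly with the channel index.
#' Only the shape matters downstream (recovery is measured by correlation).
#'
#' @param n_channels number of channels
#' @param lags lag axis in seconds
#' @param band one of \code{"saccade"}, \code{"fixation"}, \code{"amplitude"},
#'   \code{"novelty"}
#' @return channels x lags matrix
#' @keywords internal
true_trf_bank <- function(n_channels, lags, band) {
  out <- matrix(0, n_channels, length(lags))
  for (c in seq_len(n_channels)) {
    u <- (c - 1) / max(1, n_channels - 1)
    pars <- switch(band,
      saccade  = c(lat = 0.02 + 0.02 * u, f = 12, pol = ifelse(c %% 2, 1, -1),
                   g = 1.0),
      fixation = c(lat = 0.10 + 0.05 * u, f = 6, pol = 1, g = 1.2),
      amplitude = c(lat = 0.08 + 0.04 * u, f = 8, pol = ifelse(c %% 3, 1, -1),
                    g = 0.5),
      novelty  = c(lat = 0.15 + 0.10 * u, f = 5, pol = 1, g = 1.0),
      stop("unknown band: ", band))
    tt <- lags - pars["lat"]
    w <- ifelse(tt >= 0,
                pars["pol"] * pars["g"] * sin(2 * pi * pars["f"] * tt) *
                  exp(-tt / 0.12), 0)
    out[c, ] <- w
  }
  out
}

#' Generate a synthetic neural recording from events, features, and known TRFs
#'
#' Forward model: for each channel, the clean signal is the sum over bands of
#' the convolution of an event train (unit pulses, or pulses scaled by raw
#' feature values) with that band's ground-truth TRF. In
#' \code{"scalp-potential"} mode, 1/f noise is added. In \code{"bha-carrier"}
#' mode the clean signal amplitude-modulates a multi-tone 70-150 Hz carrier
#' (carrier x (1 + signal)) before white noise is added; \code{neural_fs}
#' must then be at least 400 Hz. Only the channels listed in
#' \code{modulated_channels} receive the novelty band.
#'
#' @param config a \code{\link{synth_config}}
#' @param truth ground truth from \code{\link{generate_gaze}}
#' @param features feature table from \code{\link{generate_feature_table}}
#' @param lag_window TRF support in seconds (length 2)
#' @param bands character subset of
#'   \code{c("saccade","fixation","amplitude","novelty")}
#' @return list of class \code{neural_recording} (see
#'   \code{\link{neural_recording}}) with attribute \code{truth} holding
#'   \code{true_trfs} (band x channel x lag array), \code{lags}, and
#'   \code{modulated_channels}
#' @export
generate_neural <- function(config, truth, features,
                            lag_window = c(-0.2, 0.6),
                            bands = c("saccade", "fixation", "amplitude",
                                      "novelty")) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 4L))
  fs <- config$neural_fs
  if (config$mode == "bha-carrier" && fs < 400)
    stop("bha-carrier mode requires neural_fs >= 400 Hz")
  ev <- truth$events
  if (any(ev$saccade_onset > config$duration_s))
    stop("events extend beyond the recording duration")
  n <- round(config$duration_s * fs)
  nc <- config$n_channels
  lags <- seq(round(lag_window[1] * fs), round(lag_window[2] * fs)) / fs
  modulated <- seq_len(config$n_modulated)
  trfs <- array(0, dim = c(length(bands), nc, length(lags)),
                dimnames = list(bands, NULL, NULL))
  clean <- matrix(0, nc, n)
  for (b in seq_along(bands)) {
    band <- bands[b]
    w <- true_trf_bank(nc, lags, band)
    ch_sel <- if (band == "novelty") modulated else seq_len(nc)
    trfs[b, ch_sel, ] <- w[ch_sel, ]
    align <- if (band %in% c("saccade", "amplitude"))
      ev$saccade_onset else ev$fixation_onset
    heights <- switch(band,
      saccade = rep(1, nrow(ev)), fixation = rep(1, nrow(ev)),
      amplitude = features$amplitude, novelty = features$novelty)
    reg <- impulse_train(align, config$duration_s, fs, heights = heights)
    contrib <- convolve_lagged(reg, t(w), lags * fs)
    clean[ch_sel, ] <- clean[ch_sel, ] + t(contrib)[ch_sel, , drop = FALSE]
  }
  if (config$mode == "scalp-potential") {
    data <- clean
    noise_sd <- config$noise_sd
    if (!is.null(config$snr)) {
      sig_rms <- sqrt(mean(clean^2))
      noise_sd <- sig_rms / config$snr
    }
    if (noise_sd > 0)
      for (c in seq_len(nc))
        data[c, ] <- data[c, ] + one_over_f_noise(n, alpha = 1, sd = noise_sd)
  } else {
    edges <- exp(seq(log(70), log(150), length.out = 9))
    centers <- sqrt(edges[-9] * edges[-1])
    tt <- (seq_len(n) - 1) / fs
    carrier <- rowSums(sapply(centers, function(f0)
      cos(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))))
    carrier <- carrier / stats::sd(carrier)
    data <- matrix(0, nc, n)
    noise_sd <- config$noise_sd
    if (!is.null(config$snr)) noise_sd <- 1 / config$snr
    for (c in seq_len(nc)) {
      am <- pmax(1 + clean[c, ], 0)
      data[c, ] <- carrier * am +
        if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    }
  }
  rec <- neural_recording(data = data, fs = fs,
                          channel_names = paste0("ch", seq_len(nc)),
                          modality = if (config$mode == "scalp-potential")
                            "scalp" else "ieeg")
  attr(rec, "truth") <- list(true_trfs = trfs, lags = lags,
                             modulated_channels = modulated, clean = clean)
  rec
}

# convolve an impulse/height train with per-channel lag kernels
# reg: length-n regressor; kernels: lags x channels; lag_samples: sample shifts
convolve_lagged <- function(reg, kernels, lag_samples) {
  n <- length(reg)
  out <- matrix(0, n, ncol(kernels))
  idx <- which(reg != 0)
  for (j in seq_along(lag_samples)) {
    s <- as.integer(round(lag_samples[j]))
    tgt <- idx + s
    ok <- tgt >= 1 & tgt <= n
    if (!any(ok)) next
    out[tgt[ok], ] <- out[tgt[ok], ] +
      outer(reg[idx[ok]], kernels[j, ])
  }
  out
}

#' Permute one feature column to construct a null feature table
#'
#' Used for calibration tests: destroys the association between the chosen
#' feature and the neural response while leaving every other column (and the
#' permuted column's marginal distribution) untouched.
#'
#' @param features a feature table (data.frame)
#' @param column name of the column to permute
#' @param seed RNG seed
#' @return the feature table with that column permuted
#' @export
make_null <- function(features, column, seed = 1L) {
  if (!column %in% names(features))
    stop("unknown column: ", column)
  set.seed(derive_seed(seed, 5L))
  features[[column]] <- features[[column]][sample.int(nrow(features))]
  features
}

# ---- plain-text writers ------------------------------------------------------

#' Write synthetic artifacts as plain-text files
#'
#' Gaze as CSV (t, x_deg, y_deg, valid), event tables as CSV, neural data as
#' CSV (channels in columns) with a JSON sidecar holding the sampling rate and
#' channel names, ground truth as JSON, and patches as PNG.
#'
#' @param gaze a \code{gaze_recording}
#' @param path output file path
#' @name synth-io
#' @export
write_gaze_csv <- function(gaze, path) {
  utils::write.csv(data.frame(t = gaze$t, x_deg = gaze$x, y_deg = gaze$y,
                              valid = gaze$valid),
                   path, row.names = FALSE)
  invisible(path)
}

#' @param events an event table (data.frame)
#' @rdname synth-io
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @param rec a \code{neural_recording}
#' @rdname synth-io
#' @export
write_neural_csv <- function(rec, path) {
  m <- t(rec$data)
  colnames(m) <- rec$channel_names
  utils::write.csv(m, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_names = rec$channel_names,
                            modality = rec$modality),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @param truth a ground-truth list
#' @rdname synth-io
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$events <- as.list(truth$events)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param patch numeric matrix in [0, 1]
#' @rdname synth-io
#' @export
write_patch_png <- function(patch, path) {
  png::writePNG(patch, path)
  invisible(path)
}
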
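# Preprocessing of scalp-like and intracranial-like recordings, and broadband
# high-frequency amplitude (BHA) extraction.

#' Construct a neural recording
#'
#' @param data channels x samples numeric matrix
#' @param fs sampling rate, Hz
#' @param channel_names character vector (defaults to ch1..chN)
#' @param positions optional channels x 3 (or x 2) coordinate matrix
#' @param adjacency optional symmetric logical channels x channels matrix
#' @param modality \code{"scalp"}, \code{"ieeg"}, or \code{"bha"}
#' @return list of class \code{neural_recording}
#' @export
neural_recording <- function(data, fs,
                             channel_names = paste0("ch", seq_len(nrow(data))),
                             positions = NULL, adjacency = NULL,
                             modality = c("scalp", "ieeg", "bha")) {
  modality <- match.arg(modality)
  data <- as.matrix(data)
  stopifnot(fs > 0, nrow(data) == length(channel_names))
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 positions = positions, adjacency = adjacency,
                 modality = modality),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording:%s> %d channels x %d samples @ %g Hz\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Scalp preprocessing: band-pass, downsample, EOG regression, outlier repair
#'
#' Zero-phase 4th-order Butterworth band-pass (0.5-64 Hz), polyphase
#' resampling to 100 Hz, least-squares regression of the EOG channels out of
#' every channel, then per-channel outlier samples (|x - median| > 4 IQR)
#' replaced by inverse-distance interpolation from the other channels
#' averaged over +-40 ms.
#'
#' @param rec a \code{neural_recording} with fs >= 128 Hz
#' @param eog optional EOG channels x samples matrix (same fs as \code{rec})
#' @param band pass band in Hz
#' @param fs_out output rate, Hz
#' @param repair repair residual outlier samples by spatial interpolation?
#'   (Needs channel positions; disable for signals, such as sparse test
#'   pulses, where large excursions are meaningful.)
#' @param denoise optional artifact-removal hook: any callable mapping a
#'   channels x samples matrix to a matrix of the same shape (e.g. a robust
#'   PCA implementation), applied after resampling and before EOG
#'   regression
#' @return preprocessed \code{neural_recording} at \code{fs_out}
#' @export
preprocess_scalp <- function(rec, eog = NULL, band = c(0.5, 64),
                             fs_out = 100, repair = TRUE, denoise = NULL) {
  stopifnot(inherits(rec, "neural_recording"))
  if (rec$fs < 128) stop("scalp preprocessing expects fs >= 128 Hz")
  bp <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  x <- filtfilt_mat(bp, rec$data)
  x <- t(resample_rate(t(x), rec$fs, fs_out))
  if (!is.null(denoise)) {
    x <- denoise(x)
    stopifnot(is.matrix(x), nrow(x) == nrow(rec$data))
  }
  if (!is.null(eog) && nrow(eog) > 0) {
    e <- t(resample_rate(t(as.matrix(eog)), rec$fs, fs_out))
    n <- min(ncol(x), ncol(e))
    x <- x[, seq_len(n), drop = FALSE]
    E <- cbind(1, t(e[, seq_len(n), drop = FALSE]))
    beta <- qr.solve(E, t(x))
    x <- x - t(E %*% beta)
  }
  if (repair)
    x <- repair_outliers(x, fs_out, positions = rec$positions, iqr_mult = 4,
                         window_s = 0.040)
  neural_recording(x, fs_out, rec$channel_names, rec$positions,
                   rec$adjacency, "scalp")
}

# replace per-channel outliers (|x - median| > iqr_mult * IQR) by
# inverse-distance weighted interpolation from other channels within +-window
repair_outliers <- function(x, fs, positions, iqr_mult = 4,
                            window_s = 0.040) {
  nc <- nrow(x); n <- ncol(x)
  med <- apply(x, 1, stats::median)
  iqr <- apply(x, 1, stats::IQR)
  out <- abs(x - med) > iqr_mult * iqr
  if (!any(out)) return(x)
  if (nc > 1 && is.null(positions))
    stop("channel positions are required to interpolate outlier samples")
  half <- round(window_s * fs)
  xr <- x
  for (c in seq_len(nc)) {
    idx <- which(out[c, ])
    if (!length(idx)) next
    others <- setdiff(seq_len(nc), c)
    if (!length(others)) {  # single channel: clamp toward the median
      xr[c, idx] <- med[c] + sign(x[c, idx] - med[c]) * iqr_mult * iqr[c]
      next
    }
    d <- sqrt(rowSums((positions[others, , drop = FALSE] -
                       matrix(positions[c, ], length(others),
                              ncol(positions), byrow = TRUE))^2))
    w <- 1 / pmax(d, 1e-6)
    w <- w / sum(w)
    for (i in idx) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      vals <- vapply(seq_along(others), function(k) {
        seg <- x[others[k], lo:hi]
        seg <- seg[!out[others[k], lo:hi]]
        if (!length(seg)) NA_real_ else mean(seg)
      }, numeric(1))
      ok <- !is.na(vals)
      xr[c, i] <- if (any(ok)) sum(w[ok] * vals[ok]) / sum(w[ok]) else med[c]
    }
  }
  xr
}

#' Intracranial preprocessing: resample, high-pass, local reference, notch
#'
#' Polyphase resampling to 600 Hz, zero-phase 4th-order Butterworth high-pass
#' at 0.5 Hz, local average referencing (each channel minus the mean of its
#' neighbors, computed from the pre-reference signals), and zero-phase FIR
#' notch filters (order 500, 2 Hz stop bandwidth) at 60 and 120 Hz.
#'
#' @param rec a \code{neural_recording}
#' @param neighbor_map list: for each channel, integer indices of its
#'   neighbors (may be empty; such channels are left unreferenced with a
#'   warning)
#' @param fs_out resampling target, Hz
#' @param notch_hz line frequencies to notch out
#' @return preprocessed \code{neural_recording}
#' @export
preprocess_ieeg <- function(rec, neighbor_map, fs_out = 600,
                            notch_hz = c(60, 120)) {
  stopifnot(inherits(rec, "neural_recording"))
  nc <- nrow(rec$data)
  if (length(neighbor_map) != nc)
    stop("neighbor_map must cover all channels")
  x <- t(resample_rate(t(rec$data), rec$fs, fs_out))
  hp <- signal::butter(4, 0.5 / (fs_out / 2), type = "high")
  x <- filtfilt_mat(hp, x)
  ref <- x
  for (c in seq_len(nc)) {
    nb <- neighbor_map[[c]]
    if (!length(nb)) {
      warning("channel ", c, " has no neighbors; left unreferenced")
      next
    }
    ref[c, ] <- x[c, ] - colMeans(x[nb, , drop = FALSE])
  }
  for (f0 in notch_hz) {
    if (f0 >= fs_out / 2) next
    # design edges at +-2 Hz: the Hamming transition of an order-500 filter
    # at 600 Hz is ~2 Hz, so the line frequency sits in the full stop band
    fir <- signal::fir1(500, c(f0 - 2, f0 + 2) / (fs_out / 2), type = "stop")
    ref <- filtfilt_mat(signal::Ma(fir), ref)
  }
  neural_recording(ref, fs_out, rec$channel_names, rec$positions,
                   rec$adjacency, "ieeg")
}

#' Broadband high-frequency amplitude (BHA)
#'
#' Filters each channel into 8 logarithmically spaced bands between 70 and
#' 150 Hz (9 geometric edges; zero-phase Chebyshev type II band-pass filters,
#' order 4, 40 dB stop-band attenuation), takes each band's envelope as the
#' magnitude of the analytic signal, sums the eight envelopes, resamples to
#' 100 Hz, and z-scores per channel.
#'
#' @param rec a \code{neural_recording} with fs >= 400 Hz
#' @param fs_out output rate, Hz
#' @param zscore z-score the result per channel?
#' @return \code{neural_recording} with modality \code{"bha"}
#' @export
compute_bha <- function(rec, fs_out = 100, zscore = TRUE) {
  stopifnot(inherits(rec, "neural_recording"))
  if (rec$fs < 400)
    stop("computing 70-150 Hz BHA requires fs >= 400 Hz")
  edges <- exp(seq(log(70), log(150), length.out = 9))
  nc <- nrow(rec$data)
  env_sum <- matrix(0, nc, ncol(rec$data))
  for (b in seq_len(8)) {
    flt <- signal::cheby2(4, 40, c(edges[b], edges[b + 1]) / (rec$fs / 2),
                          type = "pass")
    xb <- filtfilt_mat(flt, rec$data)
    for (c in seq_len(nc))
      env_sum[c, ] <- env_sum[c, ] + Mod(analytic_signal(xb[c, ]))
  }
  y <- t(resample_rate(t(env_sum), rec$fs, fs_out))
  if (zscore) y <- t(apply(y, 1, function(r) (r - mean(r)) / stats::sd(r)))
  neural_recording(y, fs_out, rec$channel_names, rec$positions,
                   rec$adjacency, "bha")
}

#' Read a neural recording written by \code{\link{write_neural_csv}}
#' @param path CSV path (expects the JSON sidecar next to it)
#' @export
read_neural_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path))
  neural_recording(t(m), meta$fs, meta$channel_names,
                   modality = meta$modality)
}
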
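#' @keywords internal
"_PACKAGE"

# ---- small shared numerical helpers -----------------------------------------

#' Synthesize 1/f^alpha Gaussian noise
#'
#' Frequency-domain synthesis: white Gaussian spectrum shaped by f^(-alpha/2)
#' in power (f^(-alpha/2) amplitude scaling applied to power alpha/2 per
#' amplitude convention), inverse FFT, real part. Output is scaled to unit
#' standard deviation before applying \code{sd}.
#'
#' @param n number of samples
#' @param alpha spectral exponent of the power spectrum (1 = pink noise)
#' @param sd target standard deviation
#' @return numeric vector of length \code{n}
#' @keywords internal
one_over_f_noise <- function(n, alpha = 1, sd = 1) {
  if (n < 2) return(stats::rnorm(n, sd = sd))
  nf <- n %/% 2
  f <- seq_len(nf) / n
  amp <- f^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf]))
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

#' Analytic signal via frequency-domain construction
#'
#' Returns the complex analytic signal whose real part is \code{x} and whose
#' modulus is the instantaneous envelope. No installed package exposes this
#' primitive, so it is provided here.
#'
#' @param x real numeric vector
#' @return complex vector, same length
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Polyphase resampling of a signal to a new sampling rate
#'
#' Thin wrapper over \code{signal::resample} using the rational ratio of the
#' two rates.
#'
#' @param x numeric vector or channels-in-columns matrix
#' @param fs_from,fs_to sampling rates in Hz
#' @keywords internal
resample_rate <- function(x, fs_from, fs_to) {
  if (abs(fs_from - fs_to) < 1e-9) return(x)
  r <- fs_to / fs_from
  # rational approximation with a bounded denominator
  best <- c(1L, 1L); err <- Inf
  for (q in 1:1000) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err < 1e-10) break
  }
  p <- best[1]; q <- best[2]
  if (is.matrix(x)) {
    apply(x, 2, function(col) as.numeric(signal::resample(col, p, q)))
  } else {
    as.numeric(signal::resample(x, p, q))
  }
}

#' Zero-phase (forward-backward) filtering of rows of a channel matrix
#' @keywords internal
filtfilt_mat <- function(filt, x) {
  if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(filt, row)))
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Binary morphology on a logical vector (flat structuring element)
#'
#' @param mask logical vector
#' @param k kernel size in samples (odd; centered)
#' @name morphology-1d
#' @keywords internal
dilate1d <- function(mask, k) {
  half <- (k - 1L) %/% 2L
  n <- length(mask)
  out <- logical(n)
  idx <- which(mask)
  for (i in idx) out[max(1L, i - half):min(n, i + half)] <- TRUE
  out
}

#' @rdname morphology-1d
#' @keywords internal
erode1d <- function(mask, k) !dilate1d(!mask, k)

#' Morphological closing (dilate then erode) of a logical vector
#' @rdname morphology-1d
#' @keywords internal
close1d <- function(mask, k) erode1d(dilate1d(mask, k), k)

#' Population skewness and excess kurtosis (uncorrected moments)
#'
#' Zero-variance input returns 0 for both, by convention.
#' @keywords internal
moment_stats <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v < .Machine$double.eps) return(c(skew = 0, kurtosis = 0))
  c(skew = mean((x - m)^3) / v^1.5,
    kurtosis = mean((x - m)^4) / v^2 - 3)
}

#' Shannon entropy of a probability vector (bits)
#' @keywords internal
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Contiguous runs of TRUE in a logical vector
#'
#' @return data.frame with columns \code{start}, \code{end} (inclusive indices)
#' @keywords internal
true_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Column z-scoring with zero-variance guard
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Derive a stream-specific RNG seed below 2^31 from a base seed
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 + offset) %% 2147483647)
}
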
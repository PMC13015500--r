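# Shared fixtures and brute-force oracles used across the test files.
# Oracles are written independently of the package internals they check.

# sliding-window median with shrinking centered windows at the edges
oracle_running_median <- function(x, k) {
  half <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    stats::median(x[(i - h):(i + h)])
  }, numeric(1))
}

# morphological closing by explicit dilation then erosion
oracle_close <- function(mask, k) {
  half <- (k - 1L) %/% 2L
  n <- length(mask)
  dil <- vapply(seq_len(n), function(i)
    any(mask[max(1, i - half):min(n, i + half)]), logical(1))
  vapply(seq_len(n), function(i)
    all(dil[max(1, i - half):min(n, i + half)]), logical(1))
}

# Cox-de Boor recursion for a single B-spline basis function
oracle_bspline <- function(x, knots, i, ord) {
  if (ord == 1)
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  d1 <- knots[i + ord - 1] - knots[i]
  d2 <- knots[i + ord] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * oracle_bspline(x, knots, i, ord - 1) else 0
  t2 <- if (d2 > 0) (knots[i + ord] - x) / d2 *
    oracle_bspline(x, knots, i + 1, ord - 1) else 0
  t1 + t2
}

# single-penalty ridge from the normal equations
oracle_ridge <- function(X, y, lambda) {
  p <- ncol(X)
  solve(crossprod(X) + diag(lambda, p), crossprod(X, y))
}

# direct per-event summation of kernel contributions (forward model)
oracle_event_summation <- function(event_idx, heights, kernel, lag_shifts, n) {
  out <- numeric(n)
  for (e in seq_along(event_idx))
    for (j in seq_along(lag_shifts)) {
      t <- event_idx[e] + lag_shifts[j]
      if (t >= 1 && t <= n) out[t] <- out[t] + heights[e] * kernel[j]
    }
  out
}

# symmetric GLCM features by explicit pair counting (one offset direction)
oracle_glcm_dir <- function(q, levels, dr, dc) {
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q)))
    for (j in seq_len(ncol(q))) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        P[q[i, j], q[i2, j2]] <- P[q[i, j], q[i2, j2]] + 1
        P[q[i2, j2], q[i, j]] <- P[q[i2, j2], q[i, j]] + 1
      }
    }
  P <- P / sum(P)
  ii <- seq_len(levels)
  mu_i <- sum(ii * rowSums(P)); mu_j <- sum(ii * colSums(P))
  sd_i <- sqrt(sum((ii - mu_i)^2 * rowSums(P)))
  sd_j <- sqrt(sum((ii - mu_j)^2 * colSums(P)))
  D <- outer(ii, ii, "-")
  c(contrast = sum(P * D^2),
    homogeneity = sum(P / (1 + abs(D))),
    correlation = if (sd_i > 0 && sd_j > 0)
      sum(P * outer(ii - mu_i, ii - mu_j)) / (sd_i * sd_j) else 0,
    asm = sum(P^2))
}

# a hand-built gaze trace: plateaus connected by raised-cosine saccades
make_saccade_trace <- function(amplitudes, fs = 500, fix_dur = 0.4,
                               noise_sd = 0, seed = 1) {
  set.seed(seed)
  t_cur <- fix_dur
  onsets <- numeric(0); offsets <- numeric(0)
  pos <- 0
  xs <- list(); dur_total <- fix_dur
  for (a in amplitudes) {
    d <- 0.0022 * a + 0.021
    onsets <- c(onsets, t_cur); offsets <- c(offsets, t_cur + d)
    t_cur <- t_cur + d + fix_dur
  }
  dur <- t_cur + fix_dur
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  pos <- 0
  for (k in seq_along(amplitudes)) {
    seg <- tt >= onsets[k] & tt < offsets[k]
    ph <- (tt[seg] - onsets[k]) / (offsets[k] - onsets[k])
    x[seg] <- pos + amplitudes[k] * (ph - sin(2 * pi * ph) / (2 * pi))
    pos <- pos + amplitudes[k]
    x[tt >= offsets[k]] <- pos
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  list(rec = gaze_recording(t = tt, x = x, y = numeric(n), fs = fs),
       onsets = onsets, offsets = offsets)
}

# small synthetic encoding problem with a known single-band kernel
make_encoding_toy <- function(seed = 1, dur = 60, fs = 100, n_ev = 150,
                              noise_sd = 0.5) {
  set.seed(seed)
  times <- sort(runif(n_ev * 2, 1, dur - 1))
  times <- times[c(TRUE, diff(times) > 0.12)][seq_len(n_ev)]
  times <- times[!is.na(times)]
  ev <- data.frame(saccade_onset = times, fixation_onset = times + 0.03)
  lags <- seq(-0.2, 0.6, by = 1 / fs)
  kern <- ifelse(lags > 0.08,
                 sin(2 * pi * 6 * (lags - 0.08)) * exp(-(lags - 0.08) / 0.1),
                 0)
  n <- round(dur * fs)
  reg <- impulse_train(ev$fixation_onset, dur, fs)
  sig <- oracle_event_summation(which(reg != 0), reg[reg != 0], kern,
                                round(lags * fs), n)
  y <- sig + rnorm(n, sd = noise_sd)
  list(events = ev, y = matrix(y, 1), fs = fs, dur = dur, lags = lags,
       kern = kern, clean = sig)
}
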
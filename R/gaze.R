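# Saccade / fixation detection from raw gaze traces.
#
# Two detector families are provided, matching the two classes of eye
# trackers used in free-viewing work: a velocity/acceleration threshold
# detector (EyeLink-style, 30 deg/s and 8000 deg/s^2), and a median-filter /
# 2-SD detector with morphological closing and a percentile rule for fixation
# onset (Tobii-style). Exclusion rules remove saccades near low-quality data
# (+-83 ms) and saccades following fixations shorter than 110 ms.

#' Construct a gaze recording
#'
#' @param t sample times in seconds, strictly increasing and uniform to
#'   within 1\% of 1/fs
#' @param x,y gaze angle in degrees of visual angle (NA where invalid)
#' @param valid logical validity flag per sample
#' @param fs sampling rate, Hz
#' @return list of class \code{gaze_recording}
#' @export
gaze_recording <- function(t, x, y, valid = rep(TRUE, length(t)), fs) {
  stopifnot(length(t) == length(x), length(t) == length(y),
            length(t) == length(valid), fs > 0)
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("sample times must be strictly increasing")
    if (any(abs(dt - 1 / fs) > 0.01 / fs))
      stop("sample times are not uniform at the stated sampling rate")
  }
  structure(list(t = t, x = x, y = y, valid = as.logical(valid), fs = fs),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              length(x$t), x$fs, length(x$t) / x$fs, 100 * mean(x$valid)))
  invisible(x)
}

#' Read a gaze recording from CSV
#'
#' Expects columns \code{t}, \code{x_deg}, \code{y_deg}, \code{valid}.
#' @param path CSV path
#' @param fs sampling rate; inferred from the time stamps when omitted
#' @export
read_gaze_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$t))
  gaze_recording(t = d$t, x = d$x_deg, y = d$y_deg,
                 valid = as.logical(d$valid), fs = fs)
}

#' Median-filter smoothing of gaze position
#'
#' Applies a 20th-order (21-sample centered window) running median to x and y.
#' Edges use shrinking centered windows. Invalid (NA) samples are linearly
#' interpolated before filtering and restored to NA afterwards so that the
#' filter output is defined on valid runs.
#'
#' @param rec a \code{gaze_recording}
#' @param order filter order (window = order + 1 samples; window forced odd)
#' @return smoothed \code{gaze_recording}
#' @export
smooth_gaze <- function(rec, order = 20L) {
  k <- as.integer(order) + 1L
  if (k %% 2L == 0L) k <- k + 1L
  if (length(rec$t) < k)
    stop("recording too short for a ", order, "th-order median filter")
  sm <- function(v) {
    nas <- is.na(v)
    if (all(nas)) return(v)
    vi <- v
    if (any(nas))
      vi <- stats::approx(which(!nas), v[!nas], xout = seq_along(v),
                          rule = 2)$y
    out <- as.numeric(stats::runmed(vi, k, endrule = "keep"))
    # shrinking centered windows at the edges
    half <- (k - 1L) %/% 2L
    n <- length(vi)
    for (i in seq_len(min(half, n))) {
      h <- min(i - 1L, n - i)
      out[i] <- stats::median(vi[(i - h):(i + h)])
      j <- n - i + 1L
      h <- min(j - 1L, n - j)
      out[j] <- stats::median(vi[(j - h):(j + h)])
    }
    out[nas] <- NA_real_
    out
  }
  rec$x <- sm(rec$x)
  rec$y <- sm(rec$y)
  rec
}

#' Per-sample angular gaze velocity
#'
#' Euclidean norm of the per-sample (dx, dy) divided by dt; the first sample
#' copies the second. NA positions yield NA velocities.
#'
#' @param rec a \code{gaze_recording}
#' @return numeric vector of velocities in deg/s
#' @export
angular_velocity <- function(rec) {
  n <- length(rec$t)
  if (n < 2) stop("need at least 2 samples")
  dx <- diff(rec$x); dy <- diff(rec$y); dt <- diff(rec$t)
  v <- c(NA_real_, sqrt(dx^2 + dy^2) / dt)
  v[1] <- v[2]
  v
}

# acceleration: first difference of velocity / dt, first sample copies second
angular_acceleration <- function(v, fs) {
  a <- c(NA_real_, diff(v) * fs)
  a[1] <- a[2]
  a
}

#' Threshold-based saccade detection (velocity + acceleration)
#'
#' A saccade is a contiguous run of samples with velocity above
#' \code{v_thresh} that also contains at least one sample with absolute
#' acceleration above \code{a_thresh}. (A strict both-thresholds-per-sample
#' rule would split every saccade at its velocity peak, where acceleration
#' passes through zero.) Saccade onset/offset are the first/last sample of
#' the velocity run; fixation onset is taken at the saccade offset and
#' fixation duration runs to the next saccade onset.
#'
#' Velocity is estimated over a short centered window (boxcar of
#' \code{v_smooth} samples) before thresholding, as hardware parsers do;
#' raw sample-to-sample differences amplify position noise far above both
#' thresholds. Acceleration is the first difference of the windowed
#' velocity.
#'
#' @param rec a \code{gaze_recording}
#' @param v_thresh velocity threshold, deg/s
#' @param a_thresh acceleration threshold, deg/s^2
#' @param v_smooth velocity estimation window, samples (1 = raw differences)
#' @return event table (data.frame) with columns \code{saccade_onset},
#'   \code{saccade_offset}, \code{fixation_onset}, \code{fixation_duration},
#'   \code{amplitude}, \code{quality_ok}
#' @export
detect_saccades_thresholds <- function(rec, v_thresh = 30, a_thresh = 8000,
                                       v_smooth = 5L) {
  v <- angular_velocity(rec)
  if (v_smooth > 1) {
    vi <- v
    nas <- is.na(vi)
    if (all(nas)) stop("no valid velocity samples")
    if (any(nas))
      vi <- stats::approx(which(!nas), vi[!nas], xout = seq_along(vi),
                          rule = 2)$y
    vi <- stats::filter(vi, rep(1 / v_smooth, v_smooth), sides = 2)
    vi[seq_len(v_smooth %/% 2)] <- vi[v_smooth %/% 2 + 1]
    nn <- length(vi)
    vi[(nn - v_smooth %/% 2 + 1):nn] <- vi[nn - v_smooth %/% 2]
    vi <- as.numeric(vi)
    vi[nas] <- NA_real_
    v <- vi
  }
  a <- angular_acceleration(v, rec$fs)
  mask <- !is.na(v) & v > v_thresh
  runs <- true_runs(mask)
  if (nrow(runs)) {
    keep <- vapply(seq_len(nrow(runs)), function(i) {
      aa <- abs(a[runs$start[i]:runs$end[i]])
      any(!is.na(aa) & aa > a_thresh)
    }, logical(1))
    runs <- runs[keep, , drop = FALSE]
  }
  events_from_runs(rec, runs)
}

# build the event table from index runs; fixation onset = saccade offset
events_from_runs <- function(rec, runs, fixation_onset_times = NULL) {
  n_ev <- nrow(runs)
  if (n_ev == 0)
    return(data.frame(saccade_onset = numeric(0), saccade_offset = numeric(0),
                      fixation_onset = numeric(0),
                      fixation_duration = numeric(0), amplitude = numeric(0),
                      quality_ok = logical(0)))
  on <- rec$t[runs$start]
  off <- rec$t[runs$end]
  fix <- if (is.null(fixation_onset_times)) off else fixation_onset_times
  quality <- !is.na(fix)
  fix[!quality] <- off[!quality]
  dur <- c(on[-1], NA) - fix
  amp <- vapply(seq_len(n_ev), function(i)
    saccade_amplitude(rec, on[i], off[i]), numeric(1))
  data.frame(saccade_onset = on, saccade_offset = off, fixation_onset = fix,
             fixation_duration = dur, amplitude = amp, quality_ok = quality)
}

#' 2-SD saccade mask with morphological closing
#'
#' Velocity samples more than 2 standard deviations above the mean (both
#' computed over valid samples of the whole recording) are marked, then a
#' morphological closing with a flat 5-sample kernel merges short gaps such
#' as post-saccadic overshoot corrections.
#'
#' @param rec a (typically smoothed) \code{gaze_recording}
#' @param n_sd threshold in standard deviations
#' @param close_k closing kernel size in samples
#' @return logical per-sample saccade mask
#' @export
detect_saccades_sd <- function(rec, n_sd = 2, close_k = 5L) {
  if (!any(rec$valid)) stop("recording has no valid samples")
  v <- angular_velocity(rec)
  vv <- v[rec$valid & !is.na(v)]
  if (!length(vv)) stop("no valid velocity samples")
  thr <- mean(vv) + n_sd * stats::sd(vv)
  mask <- !is.na(v) & v > thr
  close1d(mask, close_k)
}

#' Fixation onset after a saccade (70th-percentile rule)
#'
#' Returns the time of the first sample after \code{saccade_onset} whose
#' velocity falls below the 70th percentile of the velocities within
#' [onset - 33 ms, onset + 120 ms] (linear-interpolation empirical
#' percentile; strict "<"). NA when no sample in the window qualifies.
#'
#' @param rec a \code{gaze_recording}
#' @param saccade_onset saccade onset time, seconds
#' @param velocity optional precomputed velocity vector
#' @return fixation onset time in seconds, or NA
#' @export
fixation_onset <- function(rec, saccade_onset, velocity = NULL) {
  v <- if (is.null(velocity)) angular_velocity(rec) else velocity
  win <- rec$t >= saccade_onset - 0.033 & rec$t <= saccade_onset + 0.120
  vw <- v[win & !is.na(v)]
  if (!length(vw)) return(NA_real_)
  p70 <- stats::quantile(vw, 0.70, type = 7, names = FALSE)
  cand <- which(rec$t > saccade_onset & !is.na(v) & v < p70)
  if (!length(cand)) return(NA_real_)
  rec$t[cand[1]]
}

#' Full Tobii-style event detection
#'
#' Smooths gaze with the 21-sample median filter, applies the 2-SD mask with
#' closing, derives saccade runs, and locates each fixation onset with the
#' 70th-percentile rule. Events whose fixation onset cannot be determined are
#' flagged \code{quality_ok = FALSE}.
#'
#' @inheritParams detect_saccades_sd
#' @return event table as in \code{\link{detect_saccades_thresholds}}
#' @export
detect_saccades_sd_events <- function(rec, n_sd = 2, close_k = 5L) {
  recs <- smooth_gaze(rec)
  mask <- detect_saccades_sd(recs, n_sd = n_sd, close_k = close_k)
  runs <- true_runs(mask)
  v <- angular_velocity(recs)
  fix <- vapply(seq_len(nrow(runs)), function(i)
    fixation_onset(recs, recs$t[runs$start[i]], velocity = v), numeric(1))
  events_from_runs(recs, runs, fixation_onset_times = fix)
}

#' Apply the data-quality and short-fixation exclusion rules
#'
#' Drops (i) saccades with any invalid sample within +-83 ms of
#' [saccade_onset, saccade_offset], and (ii) saccades whose preceding
#' fixation (time from the previous row's fixation onset to this row's
#' saccade onset) lasted less than 110 ms. The first event has no measured
#' preceding fixation and is kept under rule (ii). The operation is
#' idempotent.
#'
#' @param events event table
#' @param rec the \code{gaze_recording} the events came from
#' @param quality_pad_s pad around each saccade for rule (i), seconds
#' @param min_fixation_s preceding-fixation threshold for rule (ii), seconds
#' @return filtered event table
#' @export
apply_exclusions <- function(events, rec, quality_pad_s = 0.083,
                             min_fixation_s = 0.110) {
  if (!nrow(events)) return(events)
  bad_t <- rec$t[!rec$valid]
  near_bad <- vapply(seq_len(nrow(events)), function(i) {
    if (!length(bad_t)) return(FALSE)
    any(bad_t >= events$saccade_onset[i] - quality_pad_s &
        bad_t <= events$saccade_offset[i] + quality_pad_s)
  }, logical(1))
  prev_fix <- c(NA_real_,
                events$saccade_onset[-1] -
                  events$fixation_onset[-nrow(events)])
  short_prev <- !is.na(prev_fix) & prev_fix < min_fixation_s
  events[!near_bad & !short_prev, , drop = FALSE]
}

#' Saccade amplitude from gaze positions
#'
#' Euclidean norm of the change in (x, y) gaze angle between the samples
#' nearest to saccade onset and offset. NA positions fall back to the nearest
#' valid sample within 40 ms, else NA.
#'
#' @param rec a \code{gaze_recording}
#' @param onset,offset saccade onset/offset times, seconds
#' @return amplitude in degrees
#' @export
saccade_amplitude <- function(rec, onset, offset) {
  pos_at <- function(tt) {
    i <- which.min(abs(rec$t - tt))
    if (!is.na(rec$x[i])) return(c(rec$x[i], rec$y[i]))
    ok <- which(!is.na(rec$x) & abs(rec$t - tt) <= 0.040)
    if (!length(ok)) return(c(NA_real_, NA_real_))
    j <- ok[which.min(abs(rec$t[ok] - tt))]
    c(rec$x[j], rec$y[j])
  }
  p1 <- pos_at(onset); p2 <- pos_at(offset)
  sqrt(sum((p2 - p1)^2))
}

#' Detect eye events with either detector and apply exclusions
#'
#' @param rec a \code{gaze_recording}
#' @param detector \code{"thresholds"} (velocity/acceleration) or \code{"sd"}
#'   (median filter + 2-SD + closing + percentile fixation onset)
#' @param exclusions apply \code{\link{apply_exclusions}}?
#' @param ... passed to the detector
#' @return event table
#' @export
detect_eye_events <- function(rec, detector = c("thresholds", "sd"),
                              exclusions = TRUE, ...) {
  detector <- match.arg(detector)
  ev <- switch(detector,
               thresholds = detect_saccades_thresholds(rec, ...),
               sd = detect_saccades_sd_events(rec, ...))
  if (exclusions) ev <- apply_exclusions(ev, rec)
  ev
}
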
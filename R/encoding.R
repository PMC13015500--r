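# Banded ridge temporal-response-function (TRF) encoding models.
#
# Events and per-event features become pulse regressors; each regressor is
# expanded over a lag window; each feature space ("band") receives its own
# ridge penalty, searched sequentially in a fixed hierarchy order so that
# variance shared between features is attributed to the feature added first.
# Model quality is the cross-validated Pearson correlation r between
# predicted and observed signals; the contribution of each feature is the
# increase Delta r over the previous stage of the hierarchy.

#' Pulse train from event times
#'
#' Zeros with one pulse at the sample nearest each event time (round-half-even
#' at the analysis rate). Multiple events mapping to the same sample add up.
#'
#' @param event_times event times in seconds
#' @param duration signal duration in seconds
#' @param fs sampling rate, Hz
#' @param heights pulse heights (default unit pulses); NA heights contribute
#'   no pulse (the event is dropped from rows requiring that feature)
#' @return numeric vector of length \code{round(duration * fs)}
#' @export
impulse_train <- function(event_times, duration, fs, heights = NULL) {
  n <- round(duration * fs)
  out <- numeric(n)
  if (!length(event_times)) return(out)
  if (any(event_times < 0 | event_times > duration))
    stop("event times must lie within [0, duration]")
  if (is.null(heights)) heights <- rep(1, length(event_times))
  idx <- round(event_times * fs) + 1L  # round() is round-half-even
  idx[idx > n] <- n
  keep <- !is.na(heights)
  for (i in which(keep)) out[idx[i]] <- out[idx[i]] + heights[i]
  out
}

#' Cubic B-spline expansion of a feature
#'
#' Evaluates a cubic (order 4) B-spline basis with \code{n} functions at each
#' value. Interior knots sit at quantiles of the observed values
#' (\code{n - 4} interior knots; for the default \code{n = 5}, a single knot
#' at the median); boundary knots at the observed range, replicated to order.
#' Values outside the knot span are clamped, so the basis rows always sum to
#' one (partition of unity).
#'
#' @param values numeric feature values (NAs allowed; rows of NA returned)
#' @param n number of basis functions (>= 4)
#' @param knots optional full knot vector (length \code{n + 4}); when given,
#'   quantile placement is skipped (used by \code{predict})
#' @return length(values) x n matrix with attribute \code{"knots"}
#' @export
bspline_expand <- function(values, n = 5L, knots = NULL) {
  n <- as.integer(n)
  if (n < 4) stop("need at least 4 basis functions for a cubic spline")
  ok <- !is.na(values)
  v <- values[ok]
  if (is.null(knots)) {
    if (length(unique(v)) < n)
      stop("fewer distinct values than needed for ", n, " spline columns")
    n_int <- n - 4L
    interior <- if (n_int > 0)
      stats::quantile(v, probs = seq_len(n_int) / (n_int + 1), names = FALSE)
    else numeric(0)
    knots <- c(rep(min(v), 4), interior, rep(max(v), 4))
  }
  lo <- knots[4]; hi <- knots[length(knots) - 3]
  vc <- pmin(pmax(v, lo), hi)
  B <- splines::splineDesign(knots, vc, ord = 4, outer.ok = FALSE)
  out <- matrix(NA_real_, length(values), n)
  out[ok, ] <- B
  attr(out, "knots") <- knots
  out
}

#' Specify one regressor band of the encoding hierarchy
#'
#' @param name band name (also the feature column name for non-impulse bands)
#' @param align \code{"saccade_onset"} or \code{"fixation_onset"}
#' @param transform \code{"impulse"} (unit pulses), \code{"linear"} (pulses
#'   scaled by the feature value), or \code{"bspline"} (pulses scaled by the
#'   B-spline basis of the feature value)
#' @param column feature column; defaults to \code{name}
#' @param df number of B-spline basis functions
#' @return list of class \code{regressor_spec}
#' @export
regressor_spec <- function(name,
                           align = c("fixation_onset", "saccade_onset"),
                           transform = c("linear", "impulse", "bspline"),
                           column = name, df = 5L) {
  structure(list(name = name, align = match.arg(align),
                 transform = match.arg(transform), column = column,
                 df = as.integer(df)),
            class = "regressor_spec")
}

#' The default nine-band feature hierarchy
#'
#' Order: saccade onset, fixation onset, saccade amplitude (B-spline, aligned
#' to saccade onset), luminance, change in luminance, spectrum slope, change
#' in spectrum slope, preceding optical flow, and novelty (all aligned to
#' fixation onset). Variance shared between features is credited to the
#' earlier band.
#'
#' @return list of \code{\link{regressor_spec}}
#' @export
default_hierarchy <- function() {
  list(regressor_spec("saccade", "saccade_onset", "impulse"),
       regressor_spec("fixation", "fixation_onset", "impulse"),
       regressor_spec("amplitude", "saccade_onset", "bspline"),
       regressor_spec("luminance"),
       regressor_spec("d_luminance"),
       regressor_spec("spectrum_slope"),
       regressor_spec("d_spectrum_slope"),
       regressor_spec("optic_flow"),
       regressor_spec("novelty"))
}

# build per-band unlagged regressor matrices (T x k each)
band_regressors <- function(hierarchy, events, features, duration, fs) {
  lapply(hierarchy, function(sp) {
    times <- events[[sp$align]]
    if (sp$transform == "impulse") {
      m <- matrix(impulse_train(times, duration, fs), ncol = 1)
      colnames(m) <- sp$name
      list(mat = m, knots = NULL)
    } else if (sp$transform == "linear") {
      vals <- features[[sp$column]]
      if (is.null(vals)) stop("feature column not found: ", sp$column)
      m <- matrix(impulse_train(times, duration, fs, heights = vals),
                  ncol = 1)
      colnames(m) <- sp$name
      list(mat = m, knots = NULL)
    } else {
      vals <- features[[sp$column]]
      if (is.null(vals)) stop("feature column not found: ", sp$column)
      B <- bspline_expand(vals, n = sp$df)
      m <- sapply(seq_len(ncol(B)), function(j)
        impulse_train(times, duration, fs, heights = B[, j]))
      colnames(m) <- paste0(sp$name, "_s", seq_len(ncol(B)))
      list(mat = m, knots = attr(B, "knots"))
    }
  })
}

#' Build a lagged design matrix from regressor columns
#'
#' Every column is expanded into one column per lag over the window
#' (inclusive endpoints; \code{round((t_max - t_min) * fs) + 1} lags). The
#' weight at lag tau multiplies the regressor at t - tau, so a pulse at time
#' e contributes to the prediction over [e + t_min, e + t_max]. Boundaries
#' are zero padded.
#'
#' @param regressors named list of T x k matrices (or vectors), one per band
#' @param lag_window c(t_min, t_max) in seconds
#' @param fs sampling rate, Hz
#' @return list with \code{X} (T x p), \code{band_cols} (named list of column
#'   index vectors), \code{lag_samples}, \code{lags} (seconds), \code{fs}
#' @export
build_design <- function(regressors, lag_window, fs) {
  stopifnot(lag_window[1] < lag_window[2])
  shifts <- seq(round(lag_window[1] * fs), round(lag_window[2] * fs))
  mats <- lapply(regressors, function(r) if (is.matrix(r)) r else cbind(r))
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1) stop("all regressor columns must have equal length")
  p <- sum(vapply(mats, ncol, integer(1))) * length(shifts)
  X <- matrix(0, n, p)
  band_cols <- list()
  col <- 0L
  cn <- character(p)
  for (b in seq_along(mats)) {
    first <- col + 1L
    for (k in seq_len(ncol(mats[[b]]))) {
      v <- mats[[b]][, k]
      for (s in shifts) {
        col <- col + 1L
        if (s >= 0) {
          if (s < n) X[(1 + s):n, col] <- v[1:(n - s)]
        } else {
          if (-s < n) X[1:(n + s), col] <- v[(1 - s):n]
        }
        base_nm <- colnames(mats[[b]])[k]
        if (is.null(base_nm) || is.na(base_nm) || !nzchar(base_nm))
          base_nm <- paste0("b", b)
        cn[col] <- paste0(base_nm, "@", s)
      }
    }
    band_nm <- names(mats)[b]
    if (is.null(band_nm) || is.na(band_nm) || !nzchar(band_nm))
      band_nm <- paste0("band", b)
    band_cols[[band_nm]] <- first:col
  }
  colnames(X) <- cn
  list(X = X, band_cols = band_cols, lag_samples = shifts,
       lags = shifts / fs, fs = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Banded ridge solution
#'
#' Returns the unique minimizer of
#' \eqn{\|y - Xw\|^2 + \sum_b \lambda_b \|w_b\|^2}, computed by scaling band
#' b's columns by \eqn{1/\sqrt{\lambda_b}}, solving a standard unit-penalty
#' ridge via Cholesky, and unscaling. With equal penalties this is exactly
#' the single-penalty ridge \eqn{(X'X + \lambda I)^{-1} X'y}.
#'
#' @param X design matrix (T x p)
#' @param y response vector or T x channels matrix
#' @param lambda_per_band positive penalties, one per band
#' @param band_cols named list of column indices per band (defaults to one
#'   band covering all columns)
#' @return p x channels weight matrix
#' @export
ridge_fit <- function(X, y, lambda_per_band,
                      band_cols = list(all = seq_len(ncol(X)))) {
  if (any(lambda_per_band <= 0)) stop("all penalties must be > 0")
  if (length(lambda_per_band) != length(band_cols))
    stop("need one penalty per band")
  y <- as.matrix(y)
  s <- numeric(ncol(X))
  for (b in seq_along(band_cols))
    s[band_cols[[b]]] <- 1 / sqrt(lambda_per_band[b])
  Xs <- sweep(X, 2, s, "*")
  A <- crossprod(Xs)
  diag(A) <- diag(A) + 1
  R <- tryCatch(chol(A), error = function(e)
    stop("normal equations are singular; increase the penalties ",
         "(lambda too close to 0)", call. = FALSE))
  v <- backsolve(R, forwardsolve(t(R), crossprod(Xs, y)))
  v * s
}

# solve from precomputed Gram blocks: (D G D + diag(pen))^-1 D g, in the
# column-scaled space; returns weights in the scaled space
ridge_solve_gram <- function(G, g, pen) {
  A <- G
  diag(A) <- diag(A) + pen
  R <- chol(A)
  backsolve(R, forwardsolve(t(R), g))
}

# ---- the model ---------------------------------------------------------------

#' Fit a banded ridge TRF encoding model
#'
#' The workhorse of the package. Builds pulse regressors from the event table
#' and feature table, lags them over \code{lag_window}, and fits a banded
#' ridge regression in which every band (feature space) has its own penalty.
#' When \code{lambda} is NULL the penalties are found by the sequential
#' search: bands enter in hierarchy order; each band's penalty is swept over
#' \code{lambda_grid} (previously frozen penalties held fixed), the value
#' maximizing the mean cross-validated correlation is frozen (ties go to the
#' smallest lambda on the grid), and the next band is appended. The stagewise cross-validated r per
#' channel yields the per-feature improvement Delta r.
#'
#' Cross-validation is leave-one-trial-out (\code{cv = "loto"}) or k-fold
#' over trials (\code{cv = "kfold"}). Within each fold, feature columns are
#' scaled by the training-fold standard deviation and the response is
#' centered by its training mean; held-out data never contributes to these
#' statistics.
#'
#' @param events event table with \code{saccade_onset} and
#'   \code{fixation_onset} columns (seconds)
#' @param features data.frame of per-event feature values, rows aligned to
#'   \code{events}; may be NULL for impulse-only hierarchies
#' @param response \code{neural_recording} or channels x samples matrix
#' @param fs sampling rate of \code{response} (taken from the recording when
#'   one is supplied)
#' @param trials integer number of contiguous equal-length trials, or a
#'   factor/vector of trial labels per sample
#' @param hierarchy list of \code{\link{regressor_spec}}, in attribution order
#' @param lag_window c(t_min, t_max) seconds
#' @param lambda_grid penalty grid for the sequential search
#' @param lambda optional fixed penalties (one per band); skips the search
#' @param cv \code{"loto"} or \code{"kfold"}
#' @param nfold folds for \code{cv = "kfold"}
#' @param stages compute stagewise cross-validated r and Delta r? (Set FALSE
#'   with fixed \code{lambda} to fit weights only.)
#' @param keep_response keep the response matrix in the object (enables
#'   \code{residuals} and no-argument \code{predict})
#' @return object of class \code{trf_model}
#' @seealso \code{\link{extract_trf}}, \code{\link{compare_alignments}}
#' @export
fit_trf <- function(events, features, response, fs = NULL, trials = 10,
                    hierarchy = default_hierarchy(),
                    lag_window = c(-0.2, 0.6),
                    lambda_grid = 10^seq(-2, 5, length.out = 15),
                    lambda = NULL, cv = c("loto", "kfold"), nfold = 5,
                    stages = is.null(lambda), keep_response = TRUE) {
  cv <- match.arg(cv)
  stages <- stages  # force before `lambda` is reassigned below
  searched <- is.null(lambda)
  if (inherits(response, "neural_recording")) {
    fs <- response$fs
    Y <- t(response$data)
  } else {
    if (is.null(fs)) stop("fs is required when response is a plain matrix")
    Y <- t(as.matrix(response))
  }
  n <- nrow(Y)
  duration <- n / fs
  hier_names <- vapply(hierarchy, function(h) h$name, character(1))
  regs <- band_regressors(hierarchy, events, features, duration, fs)
  reg_mats <- stats::setNames(lapply(regs, `[[`, "mat"), hier_names)
  knots <- stats::setNames(lapply(regs, `[[`, "knots"), hier_names)
  des <- build_design(reg_mats, lag_window, fs)
  X <- des$X
  nb <- length(hierarchy)

  # trial labels per sample
  if (length(trials) == 1) {
    trial_id <- as.integer(cut(seq_len(n), breaks = trials, labels = FALSE))
  } else {
    if (length(trials) != n) stop("trials must label every sample")
    trial_id <- as.integer(factor(trials))
  }
  n_trials <- max(trial_id)
  fold_of_trial <- if (cv == "loto") seq_len(n_trials) else
    ((seq_len(n_trials) - 1L) %% nfold) + 1L
  fold_id <- fold_of_trial[trial_id]
  n_folds <- max(fold_id)
  if (n_folds < 2) stop("need at least 2 folds")

  # per-fold Gram pieces
  folds <- lapply(seq_len(n_folds), function(f) {
    idx <- which(fold_id == f)
    Xf <- X[idx, , drop = FALSE]
    list(idx = idx, G = crossprod(Xf), g = crossprod(Xf, Y[idx, , drop = FALSE]),
         cs = colSums(Xf), cs2 = colSums(Xf^2),
         ysum = colSums(Y[idx, , drop = FALSE]), n = length(idx))
  })
  G_all <- Reduce(`+`, lapply(folds, `[[`, "G"))
  g_all <- Reduce(`+`, lapply(folds, `[[`, "g"))
  cs_all <- Reduce(`+`, lapply(folds, `[[`, "cs"))
  cs2_all <- Reduce(`+`, lapply(folds, `[[`, "cs2"))
  ysum_all <- Reduce(`+`, lapply(folds, `[[`, "ysum"))

  col_sd <- function(nn, cs, cs2) {
    v <- pmax(cs2 / nn - (cs / nn)^2, 0)
    s <- sqrt(v)
    s[s < 1e-12] <- 1
    s
  }

  # cross-validated r per channel for a given set of active bands + lambdas
  cv_r <- function(active, lam) {
    cols <- unlist(des$band_cols[active], use.names = FALSE)
    pen <- numeric(length(cols))
    pos <- 0L
    for (b in seq_along(active)) {
      nb_cols <- length(des$band_cols[[active[b]]])
      pen[pos + seq_len(nb_cols)] <- lam[b]
      pos <- pos + nb_cols
    }
    r_sum <- matrix(0, 1, ncol(Y)); r_n <- 0
    r_fold <- matrix(NA_real_, n_folds, ncol(Y))
    for (f in seq_len(n_folds)) {
      ntr <- n - folds[[f]]$n
      cs_tr <- (cs_all - folds[[f]]$cs)[cols]
      s_tr <- col_sd(ntr, cs_tr, (cs2_all - folds[[f]]$cs2)[cols])
      xm <- cs_tr / ntr
      ym <- (ysum_all - folds[[f]]$ysum) / ntr
      # center X and y by training means (intercept), scale X by training SD
      Gtr <- (G_all - folds[[f]]$G)[cols, cols, drop = FALSE] -
        ntr * outer(xm, xm)
      gtr <- (g_all - folds[[f]]$g)[cols, , drop = FALSE] -
        outer(cs_tr, ym)
      Ds <- 1 / s_tr
      Gs <- Gtr * outer(Ds, Ds)
      gs <- gtr * Ds
      W <- tryCatch(ridge_solve_gram(Gs, gs, pen), error = function(e) NULL)
      if (is.null(W)) next
      pred <- X[folds[[f]]$idx, cols, drop = FALSE] %*% (W * Ds)
      yf <- Y[folds[[f]]$idx, , drop = FALSE]
      r <- vapply(seq_len(ncol(Y)), function(c) {
        if (stats::sd(yf[, c]) == 0 || stats::sd(pred[, c]) == 0)
          return(NA_real_)
        stats::cor(pred[, c], yf[, c])
      }, numeric(1))
      r_fold[f, ] <- r
    }
    if (all(is.na(r_fold))) stop("all cross-validation folds failed")
    list(mean = colMeans(r_fold, na.rm = TRUE), folds = r_fold)
  }

  hier_names_l <- hier_names
  r_per_stage <- matrix(NA_real_, ncol(Y), nb,
                        dimnames = list(colnames(Y), hier_names_l))
  r_fold_stage <- vector("list", nb)
  names(r_fold_stage) <- hier_names_l
  if (is.null(lambda)) {
    frozen <- numeric(0)
    for (k in seq_len(nb)) {
      scores <- vapply(lambda_grid, function(l)
        mean(cv_r(hier_names_l[seq_len(k)], c(frozen, l))$mean), numeric(1))
      best <- lambda_grid[which(scores >= max(scores) - 1e-12)][1]  # smallest
      frozen <- c(frozen, best)
      st <- cv_r(hier_names_l[seq_len(k)], frozen)
      r_per_stage[, k] <- st$mean
      r_fold_stage[[k]] <- st$folds
    }
    lambda <- frozen
  } else {
    if (length(lambda) != nb) stop("need one lambda per band")
    if (stages)
      for (k in seq_len(nb)) {
        st <- cv_r(hier_names_l[seq_len(k)], lambda[seq_len(k)])
        r_per_stage[, k] <- st$mean
        r_fold_stage[[k]] <- st$folds
      }
  }
  delta_r <- if (stages || searched)
    cbind(r_per_stage[, 1, drop = FALSE],
          r_per_stage[, -1, drop = FALSE] -
            r_per_stage[, -nb, drop = FALSE]) else NULL
  if (!is.null(delta_r)) colnames(delta_r) <- hier_names_l

  # final fit on all data: center X and y (intercept), scale X columns
  cols <- unlist(des$band_cols, use.names = FALSE)
  s_all <- col_sd(n, cs_all, cs2_all)
  xm_all <- cs_all / n
  ym_all <- ysum_all / n
  gts <- (g_all - outer(cs_all, ym_all)) / s_all
  Gc <- G_all - n * outer(xm_all, xm_all)
  Gs <- Gc * outer(1 / s_all, 1 / s_all)
  pen <- numeric(ncol(X))
  for (b in seq_len(nb)) pen[des$band_cols[[b]]] <- lambda[b]
  W_scaled <- ridge_solve_gram(Gs, gts, pen)
  W <- W_scaled / s_all  # weights in raw design units
  intercept <- ym_all - as.numeric(crossprod(W, xm_all))

  model <- structure(list(
    weights = W, band_cols = des$band_cols, lags = des$lags,
    lag_samples = des$lag_samples, fs = fs,
    lambda = stats::setNames(lambda, hier_names_l),
    hierarchy = hierarchy, knots = knots,
    r_per_stage = r_per_stage, delta_r = delta_r,
    r_fold_stage = r_fold_stage,
    col_sd = s_all, y_mean = ym_all, intercept = intercept,
    cv = list(scheme = cv, n_folds = n_folds, fold_id = fold_id,
              trial_id = trial_id),
    events = events, features = features,
    n_samples = n, n_channels = ncol(Y),
    response = if (keep_response) t(Y) else NULL,
    call = match.call()), class = "trf_model")
  model
}

#' Cross-validated r and per-feature Delta r of a fitted hierarchy
#'
#' Convenience wrapper around \code{\link{fit_trf}} returning only the
#' encoding result: per-channel cross-validated r per stage and the Delta r
#' of each feature.
#'
#' @inheritParams fit_trf
#' @param ... passed to \code{\link{fit_trf}}
#' @return list with \code{r_per_stage} and \code{delta_r} (channels x bands)
#' @export
crossval_delta_r <- function(events, features, response, ...) {
  m <- fit_trf(events, features, response, ..., keep_response = FALSE)
  list(r_per_stage = m$r_per_stage, delta_r = m$delta_r,
       lambda = m$lambda)
}

#' Extract the temporal response function of one band
#'
#' For impulse and linear bands, a channels x lags weight matrix (in response
#' units per unit of the raw regressor). For B-spline bands, an array
#' channels x basis x lags; when \code{at_values} is given, the TRF
#' reconstruction at those feature values (values x channels x lags) is
#' returned instead.
#'
#' @param model a \code{trf_model}
#' @param band band name
#' @param at_values feature values at which to reconstruct a spline band
#' @export
extract_trf <- function(model, band, at_values = NULL) {
  cols <- model$band_cols[[band]]
  if (is.null(cols)) stop("band not in model: ", band)
  nlag <- length(model$lags)
  k <- length(cols) / nlag
  W <- model$weights[cols, , drop = FALSE]  # (k*nlag) x channels
  arr <- array(W, dim = c(nlag, k, ncol(W)))
  if (k == 1) return(t(arr[, 1, , drop = TRUE]))  # channels x lags
  if (is.null(at_values)) return(aperm(arr, c(3, 2, 1)))
  B <- bspline_expand(at_values, n = k, knots = model$knots[[band]])
  out <- array(0, dim = c(length(at_values), ncol(W), nlag))
  for (v in seq_along(at_values))
    for (j in seq_len(k))
      out[v, , ] <- out[v, , ] + B[v, j] * t(arr[, j, ])
  out
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d bands, %d channels, %d lags (%.2f..%.2f s)\n",
              length(x$band_cols), x$n_channels, length(x$lags),
              min(x$lags), max(x$lags)))
  cat("  lambda:", paste(sprintf("%s=%.3g", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  if (!is.null(x$r_per_stage) && !all(is.na(x$r_per_stage)))
    cat(sprintf("  mean cross-validated r (full model): %.4f\n",
                mean(x$r_per_stage[, ncol(x$r_per_stage)], na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.trf_model <- function(object, ...) {
  tab <- data.frame(band = names(object$lambda),
                    lambda = as.numeric(object$lambda))
  if (!is.null(object$delta_r)) {
    tab$mean_delta_r <- colMeans(object$delta_r, na.rm = TRUE)
    tab$max_delta_r <- apply(object$delta_r, 2, max, na.rm = TRUE)
  }
  structure(list(table = tab, cv = object$cv,
                 n_channels = object$n_channels), class = "summary.trf_model")
}

#' @export
print.summary.trf_model <- function(x, ...) {
  cat(sprintf("Banded ridge TRF model: %d channels, %s cross-validation (%d folds)\n",
              x$n_channels, x$cv$scheme, x$cv$n_folds))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.trf_model <- function(object, ...) {
  stats::setNames(lapply(names(object$band_cols), function(b)
    extract_trf(object, b)), names(object$band_cols))
}

#' Predict neural activity from a fitted TRF model
#'
#' With no new data, returns the fitted values on the training series.
#' Otherwise rebuilds the design from the supplied events/features.
#'
#' @param object a \code{trf_model}
#' @param events,features new event/feature tables (optional)
#' @param duration duration of the predicted series in seconds (required with
#'   new events)
#' @param ... unused
#' @return channels x samples matrix of predictions
#' @export
predict.trf_model <- function(object, events = NULL, features = NULL,
                              duration = NULL, ...) {
  if (is.null(events)) {
    events <- object$events; features <- object$features
    duration <- object$n_samples / object$fs
  }
  if (is.null(duration)) stop("duration is required with new events")
  regs <- band_regressors(object$hierarchy, events, features, duration,
                          object$fs)
  reg_mats <- stats::setNames(lapply(regs, `[[`, "mat"),
                              names(object$band_cols))
  des <- build_design(reg_mats,
                      c(min(object$lags), max(object$lags)), object$fs)
  pred <- des$X %*% object$weights
  t(pred + matrix(object$intercept, nrow(pred), length(object$intercept),
                  byrow = TRUE))
}

#' @export
residuals.trf_model <- function(object, ...) {
  if (is.null(object$response))
    stop("model was fitted with keep_response = FALSE")
  object$response - stats::predict(object)
}

#' Simulate responses from a fitted TRF model
#'
#' Fitted values plus Gaussian noise with the residual standard deviation of
#' each channel.
#'
#' @param object a \code{trf_model}
#' @param nsim number of simulated response matrices
#' @param seed RNG seed
#' @param ... unused
#' @return list of channels x samples matrices
#' @export
simulate.trf_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- stats::residuals(object)
  fit <- stats::predict(object)
  sds <- apply(res, 1, stats::sd)
  lapply(seq_len(nsim), function(i)
    fit + matrix(stats::rnorm(length(fit)), nrow(fit)) * sds)
}

#' Plot TRF weight curves
#'
#' @param x a \code{trf_model}
#' @param band band to plot (default: last band of the hierarchy)
#' @param channels channel indices (default: all)
#' @param ... passed to \code{matplot}
#' @export
plot.trf_model <- function(x, band = utils::tail(names(x$band_cols), 1),
                           channels = NULL, ...) {
  trf <- extract_trf(x, band)
  if (length(dim(trf)) == 3) trf <- apply(trf, c(1, 3), mean)
  if (!is.null(channels)) trf <- trf[channels, , drop = FALSE]
  graphics::matplot(x$lags, t(trf), type = "l", lty = 1,
                    xlab = "lag (s)", ylab = "TRF weight",
                    main = paste0(band, " temporal response function"), ...)
  graphics::abline(v = 0, h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Compare saccade- and fixation-locked encoding variants
#'
#' Fits onset-only, onset + amplitude, and onset + amplitude + novelty models
#' with every regressor locked to either saccade onset or fixation onset, and
#' returns the cross-validated r of each variant together with the
#' improvement over the previous variant.
#'
#' @inheritParams fit_trf
#' @param lambda_grid penalty grid (kept small here; these are comparison
#'   fits, not the full hierarchy)
#' @return data.frame: alignment, variant, mean r, mean improvement
#' @export
compare_alignments <- function(events, features, response, fs = NULL,
                               trials = 10, lag_window = c(-0.2, 0.6),
                               lambda_grid = 10^seq(-1, 3, length.out = 5),
                               cv = "loto") {
  out <- NULL
  for (al in c("saccade_onset", "fixation_onset")) {
    hier <- list(regressor_spec("onset", al, "impulse"),
                 regressor_spec("amplitude", al, "linear"),
                 regressor_spec("novelty", al, "linear"))
    m <- crossval_delta_r(events, features, response, fs = fs,
                          trials = trials, hierarchy = hier,
                          lag_window = lag_window,
                          lambda_grid = lambda_grid, cv = cv)
    r <- colMeans(m$r_per_stage, na.rm = TRUE)
    dr <- colMeans(m$delta_r, na.rm = TRUE)
    out <- rbind(out, data.frame(
      alignment = sub("_onset", "", al),
      variant = c("onset", "onset+amplitude", "onset+amplitude+novelty"),
      r = as.numeric(r), delta_r = as.numeric(dr)))
  }
  out
}
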
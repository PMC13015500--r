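# Pipeline orchestration: configuration, validation, and the download-free
# end-to-end demonstration on synthetic data.

#' Build a pipeline configuration
#'
#' Defaults run the synthetic end-to-end demonstration: generate gaze,
#' features, and neural data with novelty planted in a subset of channels;
#' detect events from the gaze trace; fit the banded ridge TRF hierarchy;
#' bootstrap the per-trial novelty improvement per channel; FDR-correct; and
#' report flagged channels.
#'
#' @param synth a \code{\link{synth_config}} (the data source)
#' @param detector \code{"thresholds"} or \code{"sd"}
#' @param hierarchy list of \code{\link{regressor_spec}}; default: saccade,
#'   fixation, amplitude (B-spline), novelty
#' @param lag_window lag window, seconds
#' @param lambda_grid penalty grid for the sequential search
#' @param cv \code{"loto"} or \code{"kfold"}
#' @param n_trials number of contiguous trials (cross-validation units)
#' @param n_boot bootstrap resamples for channel significance
#' @param alpha FDR level
#' @param seed pipeline seed
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(synth = synth_config(),
                            detector = "thresholds",
                            hierarchy = list(
                              regressor_spec("saccade", "saccade_onset",
                                             "impulse"),
                              regressor_spec("fixation", "fixation_onset",
                                             "impulse"),
                              regressor_spec("amplitude", "saccade_onset",
                                             "bspline"),
                              regressor_spec("novelty", "fixation_onset",
                                             "linear")),
                            lag_window = c(-0.2, 0.6),
                            lambda_grid = 10^seq(-1, 3, length.out = 5),
                            cv = "loto", n_trials = 12,
                            n_boot = 1000, alpha = 0.05, seed = 1L) {
  structure(list(synth = synth, detector = detector, hierarchy = hierarchy,
                 lag_window = lag_window, lambda_grid = lambda_grid,
                 cv = cv, n_trials = n_trials, n_boot = n_boot,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks with actionable messages. Returns TRUE
#' invisibly when the configuration is valid; otherwise stops (or, with
#' \code{stop_on_error = FALSE}, returns the character vector of problems).
#'
#' @param config a \code{pipeline_config}
#' @param stop_on_error stop at the first report?
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  probs <- character(0)
  if (!inherits(config, "pipeline_config"))
    probs <- c(probs, "not a pipeline_config object")
  lw <- config$lag_window
  if (length(lw) != 2 || !(lw[1] < lw[2]))
    probs <- c(probs, sprintf(
      "lag window must satisfy t_min < t_max (got [%s, %s])",
      lw[1], lw[2]))
  if (any(config$lambda_grid <= 0))
    probs <- c(probs, "lambda grid must be strictly positive")
  if (!config$detector %in% c("thresholds", "sd"))
    probs <- c(probs, sprintf("unknown detector '%s' (use 'thresholds' or 'sd')",
                              config$detector))
  if (!config$cv %in% c("loto", "kfold"))
    probs <- c(probs, sprintf("unknown cv scheme '%s'", config$cv))
  known <- c("saccade", "fixation", "amplitude", "luminance", "d_luminance",
             "spectrum_slope", "d_spectrum_slope", "optic_flow", "novelty")
  for (sp in config$hierarchy) {
    nm <- sp$name
    if (!nm %in% known) {
      near <- known[which.min(utils::adist(nm, known))]
      probs <- c(probs, sprintf(
        "unknown feature '%s' in hierarchy (did you mean '%s'?)", nm, near))
    }
  }
  if (length(lw) == 2 && lw[1] < lw[2] &&
      diff(lw) * config$synth$neural_fs < 2)
    probs <- c(probs, "lag window shorter than two samples at neural_fs")
  if (config$n_trials < 2)
    probs <- c(probs, "need at least 2 trials for cross-validation")
  if (length(probs)) {
    if (stop_on_error) stop(paste(probs, collapse = "\n  "), call. = FALSE)
    return(probs)
  }
  invisible(TRUE)
}

#' Run the full synthetic pipeline
#'
#' Executes generate -> detect -> encode -> test and (optionally) writes all
#' artifacts to \code{out_dir} as plain-text files: gaze and event CSVs, the
#' feature table, the fitted TRF weights and penalties (JSON), the
#' statistical report (JSON), and a structured log with stage timings.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir output directory (NULL: return results without writing)
#' @param verbose print stage progress?
#' @return list: \code{events}, \code{features}, \code{model}
#'   (\code{trf_model}), \code{report} (per-channel novelty Delta r,
#'   bootstrap p, q, significance mask), \code{truth}, \code{log}
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  validate_config(config)
  t_start <- proc.time()[3]
  log <- list(seed = config$seed)
  stage <- function(what, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    log[[paste0("t_", what)]] <<- round(proc.time()[3] - t0, 3)
    if (verbose) message(sprintf("[%s] %.2fs", what, proc.time()[3] - t0))
    res
  }
  sc <- config$synth
  sc$seed <- derive_seed(config$seed, sc$seed)
  gz <- stage("simulate", generate_gaze(sc))
  feats_true <- stage("features", generate_feature_table(sc, gz$truth))
  rec <- stage("neural", generate_neural(sc, gz$truth, feats_true,
                                         lag_window = config$lag_window))
  ev_det <- stage("detect", detect_eye_events(gz$gaze,
                                              detector = config$detector))
  # associate detected events with generated features via nearest true event
  truth_ev <- gz$truth$events
  match_idx <- vapply(ev_det$saccade_onset, function(t0)
    which.min(abs(truth_ev$saccade_onset - t0)), integer(1))
  feats <- feats_true[match_idx, , drop = FALSE]
  feats$amplitude <- ev_det$amplitude  # measured, not true, amplitude
  model <- stage("encode", fit_trf(
    ev_det, feats, rec, trials = config$n_trials,
    hierarchy = config$hierarchy, lag_window = config$lag_window,
    lambda_grid = config$lambda_grid, cv = config$cv,
    keep_response = FALSE))
  report <- stage("stats", {
    dr_fold <- delta_r_by_fold(model)
    hb <- hierarchical_bootstrap(dr_fold, upper = seq_len(nrow(dr_fold)),
                                 n_boot = config$n_boot,
                                 seed = derive_seed(config$seed, 77L))
    f <- fdr_bh(hb$p, config$alpha)
    list(delta_r = colMeans(dr_fold), p_boot = hb$p, q = f$q,
         significant = f$mask, n_boot = config$n_boot)
  })
  log$t_total <- round(proc.time()[3] - t_start, 3)
  out <- list(events = ev_det, features = feats, model = model,
              report = report, truth = gz$truth, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gaze_csv(gz$gaze, file.path(out_dir, "gaze.csv"))
    write_events_csv(ev_det, file.path(out_dir, "events.csv"))
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(lambda = as.list(model$lambda),
           lags = model$lags,
           weights = lapply(names(model$band_cols), function(b) {
             w <- extract_trf(model, b)
             if (length(dim(w)) == 3) apply(w, c(1, 3), mean) else w
           })),
      file.path(out_dir, "model.json"), digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Per-fold, per-channel Delta r of one band
#'
#' Fold-level held-out r of the hierarchy up to \code{band} minus that of
#' the hierarchy up to the previous band, taken from the stagewise
#' cross-validation records of a fitted model (requires
#' \code{fit_trf(..., stages = TRUE)} or a searched fit). These fold-level
#' values are the units entering \code{\link{hierarchical_bootstrap}}.
#'
#' @param model a \code{trf_model}
#' @param band band name (default: the last band of the hierarchy)
#' @return folds x channels matrix
#' @export
delta_r_by_fold <- function(model, band = NULL) {
  rf <- model$r_fold_stage
  if (is.null(rf) || all(vapply(rf, is.null, logical(1))))
    stop("model was fitted with stages = FALSE; refit with stages = TRUE")
  nb <- length(rf)
  k <- if (is.null(band)) nb else match(band, names(rf))
  if (is.na(k) || k < 2) stop("band must be a non-first band of the model")
  rf[[k]] - rf[[k - 1]]
}

#' Read and write pipeline configurations as YAML
#'
#' The YAML mirrors the \code{\link{pipeline_config}} fields; the hierarchy
#' is a list of (name, align, transform) entries.
#'
#' @param path YAML file path
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  hier <- lapply(y$hierarchy, function(h)
    regressor_spec(h$name, h$align, h$transform,
                   column = h$column %||% h$name,
                   df = h$df %||% 5L))
  sy <- y$synth %||% list()
  synth <- do.call(synth_config, sy)
  pipeline_config(synth = synth, detector = y$detector %||% "thresholds",
                  hierarchy = hier,
                  lag_window = as.numeric(y$lag_window %||% c(-0.2, 0.6)),
                  lambda_grid = as.numeric(y$lambda_grid %||%
                                             10^seq(-1, 3, length.out = 5)),
                  cv = y$cv %||% "loto",
                  n_trials = y$n_trials %||% 12,
                  n_boot = y$n_boot %||% 1000,
                  alpha = y$alpha %||% 0.05,
                  seed = y$seed %||% 1L)
}

#' @param config a \code{pipeline_config}
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- list(
    synth = unclass(config$synth),
    detector = config$detector,
    hierarchy = lapply(config$hierarchy, function(h)
      list(name = h$name, align = h$align, transform = h$transform,
           column = h$column, df = h$df)),
    lag_window = config$lag_window, lambda_grid = config$lambda_grid,
    cv = config$cv, n_trials = config$n_trials, n_boot = config$n_boot,
    alpha = config$alpha, seed = config$seed)
  y$synth$snr <- if (is.null(config$synth$snr)) NULL else config$synth$snr
  yaml::write_yaml(y, path)
  invisible(path)
}
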
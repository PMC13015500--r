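# Statistical layer: hierarchical bootstrap of encoding improvements,
# FDR correction, spatiotemporal cluster permutation tests on TRF weights,
# peak characterization, enhancement/suppression classification, saccadic
# spike-artifact electrode detection, and condition comparisons.

#' Hierarchical bootstrap p-values for encoding improvements
#'
#' Two-level bootstrap respecting nesting (e.g. participants containing
#' chapters): upper units are resampled with replacement, then lower units
#' within each sampled upper unit. The p-value is the fraction of bootstrap
#' means at or below zero (one-sided test of improvement > 0), floored at
#' 1/n_boot. With a single upper unit the procedure degrades to an ordinary
#' one-level bootstrap over lower units, with a warning.
#'
#' @param values numeric vector (one value per lowest unit) or units x
#'   channels matrix
#' @param upper upper-level grouping factor per lowest unit
#' @param lower lower-level labels per lowest unit (defaults to one lower
#'   unit per row)
#' @param n_boot number of bootstrap resamples
#' @param seed RNG seed
#' @return list: \code{p} (per channel), \code{boot_means} (n_boot x
#'   channels), \code{n_boot}
#' @export
hierarchical_bootstrap <- function(values, upper,
                                   lower = seq_along(upper),
                                   n_boot = 10000, seed = 1L) {
  V <- as.matrix(values)
  upper <- as.factor(upper)
  if (length(upper) != nrow(V)) stop("grouping must label every value row")
  ulev <- levels(upper)
  if (length(ulev) == 1)
    warning("single upper unit: degrading to a one-level bootstrap")
  rows_of <- split(seq_len(nrow(V)), upper)
  set.seed(derive_seed(seed, 11L))
  bm <- matrix(NA_real_, n_boot, ncol(V))
  n_up <- length(ulev)
  for (b in seq_len(n_boot)) {
    us <- sample.int(n_up, n_up, replace = TRUE)
    idx <- unlist(lapply(us, function(u) {
      r <- rows_of[[u]]
      r[sample.int(length(r), length(r), replace = TRUE)]
    }), use.names = FALSE)
    bm[b, ] <- colMeans(V[idx, , drop = FALSE])
  }
  p <- pmax(colMeans(bm <= 0), 1 / n_boot)
  list(p = p, boot_means = bm, n_boot = n_boot)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure; returns the adjusted values (monotone q, via
#' \code{p.adjust}) and the significance mask at \code{alpha}.
#'
#' @param p_values p-values in [0, 1]
#' @param alpha FDR level
#' @return list with \code{q} and logical \code{mask}
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, mask = !is.na(q) & q <= alpha)
}

#' Spatiotemporal cluster permutation test on TRF stacks
#'
#' One-sample t statistics per channel x lag over viewings; samples with
#' |t| above the two-sided critical value at \code{cluster_alpha} are
#' clustered by spatial adjacency and temporal contiguity (same sign within a
#' cluster); the cluster statistic is the sum of t. The null distribution of
#' the maximum |cluster statistic| comes from sign-flipping whole viewings;
#' cluster p = (1 + #\{null max >= observed\}) / (1 + n_perm).
#'
#' @param trf_stack viewings x channels x lags array
#' @param adjacency symmetric logical channels x channels matrix
#' @param n_perm number of sign-flip permutations
#' @param cluster_alpha per-sample two-sided alpha forming clusters
#' @param seed RNG seed
#' @return list: \code{clusters} (list of data.frames with channel/lag
#'   members), \code{cluster_stat}, \code{p}, \code{t} (channels x lags
#'   matrix), \code{threshold}
#' @export
cluster_permutation <- function(trf_stack, adjacency, n_perm = 10000,
                                cluster_alpha = 0.01, seed = 1L) {
  d <- dim(trf_stack)
  if (length(d) != 3) stop("trf_stack must be viewings x channels x lags")
  V <- d[1]; C <- d[2]; L <- d[3]
  if (nrow(adjacency) != C || ncol(adjacency) != C)
    stop("adjacency must cover all channels")
  if (!isSymmetric(adjacency * 1)) stop("adjacency must be symmetric")
  M <- matrix(trf_stack, V, C * L)  # cells in channel-major order
  thr <- stats::qt(1 - cluster_alpha / 2, df = V - 1)
  ss <- colSums(M^2)                # invariant under sign flips
  t_of <- function(mu) {
    vv <- pmax((ss - V * mu^2) / (V - 1), 0)
    se <- sqrt(vv / V)
    ifelse(se > 0, mu / se, 0)
  }
  nb_list <- lapply(seq_len(C), function(c) which(adjacency[c, ]))
  t_obs <- t_of(colMeans(M))
  obs <- find_clusters(t_obs, thr, C, L, adjacency, nb_list = nb_list)
  set.seed(derive_seed(seed, 13L))
  S <- matrix(sample(c(-1, 1), n_perm * V, replace = TRUE), n_perm, V)
  Mu <- (S %*% M) / V
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    tp <- t_of(Mu[p, ])
    null_max[p] <- max_cluster_stat(tp, thr, C, L, nb_list)
  }
  pvals <- vapply(obs$stat, function(s)
    (1 + sum(null_max >= abs(s))) / (1 + n_perm), numeric(1))
  list(clusters = obs$members, cluster_stat = obs$stat, p = pvals,
       t = matrix(t_obs, C, L), threshold = thr, n_perm = n_perm,
       null_max = null_max)
}

# connected components of supra-threshold cells on the channels x lags grid;
# neighbors: same channel adjacent lag, or adjacent channel same lag;
# positive and negative t cluster separately. Cells are indexed
# channel-major: id = ch + (lag - 1) * C.
find_clusters <- function(t_flat, thr, C, L, adjacency,
                          nb_list = lapply(seq_len(C), function(c)
                            which(adjacency[c, ]))) {
  supra <- which(abs(t_flat) > thr)
  if (!length(supra))
    return(list(members = list(), stat = numeric(0)))
  n_s <- length(supra)
  sgn <- sign(t_flat[supra])
  # map cell id -> index within `supra` (0 = not supra)
  slot <- integer(C * L)
  slot[supra] <- seq_len(n_s)
  ch <- ((supra - 1L) %% C) + 1L
  lab <- integer(n_s)
  cur <- 0L
  queue <- integer(n_s)
  for (i in seq_len(n_s)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    lab[i] <- cur
    queue[1] <- i; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      j <- queue[qh]; qh <- qh + 1L
      id <- supra[j]
      cand <- c(id - C, id + C, id - ch[j] + nb_list[[ch[j]]])
      cand <- cand[cand >= 1L & cand <= C * L]
      hits <- slot[cand]
      hits <- hits[hits > 0L]
      hits <- hits[lab[hits] == 0L & sgn[hits] == sgn[j]]
      if (length(hits)) {
        lab[hits] <- cur
        queue[(qt + 1L):(qt + length(hits))] <- hits
        qt <- qt + length(hits)
      }
    }
  }
  members <- lapply(seq_len(cur), function(k) {
    ids <- supra[lab == k]
    data.frame(ch = ((ids - 1L) %% C) + 1L, lag = ((ids - 1L) %/% C) + 1L)
  })
  stat <- vapply(seq_len(cur), function(k)
    sum(t_flat[supra[lab == k]]), numeric(1))
  list(members = members, stat = stat)
}

# maximum |sum of t| over clusters, membership not materialized (null perms)
max_cluster_stat <- function(t_flat, thr, C, L, nb_list) {
  supra <- which(abs(t_flat) > thr)
  if (!length(supra)) return(0)
  n_s <- length(supra)
  sgn <- sign(t_flat[supra])
  slot <- integer(C * L)
  slot[supra] <- seq_len(n_s)
  ch <- ((supra - 1L) %% C) + 1L
  lab <- integer(n_s)
  cur <- 0L
  queue <- integer(n_s)
  best <- 0
  for (i in seq_len(n_s)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    lab[i] <- cur
    tot <- t_flat[supra[i]]
    queue[1] <- i; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      j <- queue[qh]; qh <- qh + 1L
      id <- supra[j]
      cand <- c(id - C, id + C, id - ch[j] + nb_list[[ch[j]]])
      cand <- cand[cand >= 1L & cand <= C * L]
      hits <- slot[cand]
      hits <- hits[hits > 0L]
      hits <- hits[lab[hits] == 0L & sgn[hits] == sgn[j]]
      if (length(hits)) {
        lab[hits] <- cur
        tot <- tot + sum(t_flat[supra[hits]])
        queue[(qt + 1L):(qt + length(hits))] <- hits
        qt <- qt + length(hits)
      }
    }
    if (abs(tot) > best) best <- abs(tot)
  }
  best
}

#' Peak magnitude, latency, and sign of a TRF
#'
#' Magnitude is the maximum of |TRF|; latency the lag of that sample (ties
#' resolved to the earliest lag); sign the sign of the TRF there.
#'
#' @param trf numeric vector of TRF weights
#' @param lag_axis lags in seconds, same length
#' @return list: \code{magnitude}, \code{latency}, \code{sign}
#' @export
trf_peak <- function(trf, lag_axis) {
  if (!length(trf)) stop("empty TRF")
  i <- which.max(abs(trf))  # which.max returns the first (earliest) maximum
  list(magnitude = abs(trf[i]), latency = lag_axis[i],
       sign = as.numeric(sign(trf[i])))
}

#' Significance of TRF peaks via bootstrap + FDR
#'
#' For each channel, a two-sided bootstrap p-value of the TRF value at that
#' channel's peak lag (fraction of replicates crossing zero, doubled, floored
#' at 1/n_boot), followed by FDR correction across channels.
#'
#' @param trf_boots replicates x channels matrix of TRF values sampled at
#'   each channel's peak lag
#' @param alpha FDR level
#' @return list: \code{p}, \code{q}, \code{mask}
#' @export
peak_significance <- function(trf_boots, alpha = 0.05) {
  B <- nrow(trf_boots)
  p <- vapply(seq_len(ncol(trf_boots)), function(c) {
    b <- trf_boots[, c]
    min(1, max(2 * min(mean(b <= 0), mean(b >= 0)), 1 / B))
  }, numeric(1))
  f <- fdr_bh(p, alpha)
  list(p = p, q = f$q, mask = f$mask)
}

#' Classify a novelty modulation as enhancement or suppression
#'
#' Enhancement when the novelty TRF at its own peak lag has the same sign as
#' the baseline fixation TRF at that lag; suppression otherwise. When the
#' baseline at that lag is below 10\% of the baseline's own peak magnitude,
#' the classification is flagged indeterminate.
#'
#' @param novelty_trf,baseline_fixation_trf TRFs on the same lag axis
#' @param lag_axis lags in seconds
#' @return character: \code{"enhancement"}, \code{"suppression"}, or
#'   \code{"indeterminate"}
#' @export
classify_modulation <- function(novelty_trf, baseline_fixation_trf,
                                lag_axis) {
  stopifnot(length(novelty_trf) == length(baseline_fixation_trf))
  pk <- trf_peak(novelty_trf, lag_axis)
  i <- which(lag_axis == pk$latency)[1]
  base_val <- baseline_fixation_trf[i]
  base_peak <- max(abs(baseline_fixation_trf))
  if (base_peak == 0 || abs(base_val) < 0.10 * base_peak)
    return("indeterminate")
  if (sign(base_val) == pk$sign) "enhancement" else "suppression"
}

#' Detect electrodes carrying saccadic spike artifacts
#'
#' Correlates saccade-locked TRFs across channels, clusters channels by
#' average linkage on 1 - r, and flags clusters whose mean TRF (i) has its
#' absolute peak within +-20 ms of saccade onset and (ii) concentrates more
#' than \code{energy_thresh} of its energy within +-30 ms of onset (a
#' stereotyped biphasic extraocular-muscle potential).
#'
#' @param saccade_trfs channels x lags matrix of saccade-locked TRFs
#' @param lag_axis lags in seconds
#' @param cut_h dendrogram cut height on the 1 - r scale
#' @param peak_window_s peak-latency criterion half width, seconds
#' @param energy_window_s energy-concentration window half width, seconds
#' @param energy_thresh energy-fraction threshold
#' @return list: \code{excluded} (channel indices), \code{cluster} (labels),
#'   \code{hclust}, \code{diagnostics} (per-cluster peak latency and energy
#'   fraction)
#' @export
detect_spike_artifact_channels <- function(saccade_trfs, lag_axis,
                                           cut_h = 0.5,
                                           peak_window_s = 0.020,
                                           energy_window_s = 0.030,
                                           energy_thresh = 0.6) {
  nc <- nrow(saccade_trfs)
  if (nc < 3) stop("need at least 3 channels")
  R <- suppressWarnings(stats::cor(t(saccade_trfs)))
  R[!is.finite(R)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
  cl <- stats::cutree(hc, h = cut_h)
  near <- abs(lag_axis) <= energy_window_s
  diag_tab <- NULL
  excluded <- integer(0)
  for (k in sort(unique(cl))) {
    mtrf <- colMeans(saccade_trfs[cl == k, , drop = FALSE])
    pk <- trf_peak(mtrf, lag_axis)
    efrac <- sum(mtrf[near]^2) / max(sum(mtrf^2), .Machine$double.eps)
    spike <- abs(pk$latency) <= peak_window_s && efrac > energy_thresh
    if (spike) excluded <- c(excluded, which(cl == k))
    diag_tab <- rbind(diag_tab,
                      data.frame(cluster = k, n = sum(cl == k),
                                 peak_latency = pk$latency,
                                 energy_fraction = efrac, flagged = spike))
  }
  list(excluded = sort(excluded), cluster = cl, hclust = hc,
       diagnostics = diag_tab)
}

#' Paired comparison of modulation magnitudes between conditions
#'
#' Paired t-test (e.g. movie vs image viewing across shared channels). A
#' constant nonzero difference with zero variance is reported with
#' \code{t = Inf * sign} and a floored p-value; identical vectors give
#' t = 0, p = 1.
#'
#' @param mags_a,mags_b paired magnitude vectors
#' @return list: \code{t}, \code{df}, \code{p}, \code{mean_diff}
#' @export
compare_conditions <- function(mags_a, mags_b) {
  stopifnot(length(mags_a) == length(mags_b))
  d <- mags_a - mags_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    return(list(t = Inf * sign(mean(d)), df = n - 1,
                p = .Machine$double.xmin, mean_diff = mean(d)))
  }
  tt <- stats::t.test(mags_a, mags_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' Per-region summary of channel values
#'
#' Mean and count per region label; channels labeled \code{"unknown"} are
#' excluded; empty regions are absent from the output.
#'
#' @param values_per_channel numeric vector
#' @param region_labels character labels, same length
#' @return data.frame: region, mean, n
#' @export
region_summary <- function(values_per_channel, region_labels) {
  stopifnot(length(values_per_channel) == length(region_labels))
  keep <- region_labels != "unknown" & !is.na(region_labels)
  if (!any(keep))
    return(data.frame(region = character(0), mean = numeric(0),
                      n = integer(0)))
  sp <- split(values_per_channel[keep], region_labels[keep])
  data.frame(region = names(sp),
             mean = vapply(sp, mean, numeric(1)),
             n = vapply(sp, length, integer(1)), row.names = NULL)
}
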
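# Spatiotemporal cluster statistics on within-participant walking-minus-
# sitting ERP differences: pointwise one-sample t-maps, weighted-cluster-mass
# clustering over an electrode neighborhood graph, and Monte Carlo sign-flip
# permutation inference (paired-design exchangeability).

#' Electrode neighborhood graph from montage positions
#'
#' Electrodes whose chord distance on the unit sphere is at most `max_dist`
#' are neighbors. The default gives roughly 6-8 neighbors per electrode on
#' the standard 64-channel montage.
#'
#' @param montage montage data.frame (see [montage_biosemi64()])
#' @param max_dist neighbor distance threshold (chord length, unit sphere)
#' @return list of class `adjacency_graph`: `matrix` (symmetric logical,
#'   zero diagonal), `neighbors` (list of 1-based index vectors), `max_dist`,
#'   `mean_degree`
#' @export
build_adjacency <- function(montage, max_dist = 0.45) {
  d <- montage_distances(montage)
  A <- d > 0 & d <= max_dist
  diag(A) <- FALSE
  deg <- rowSums(A)
  if (any(deg == 0) && max_dist > 0)
    warning(sum(deg == 0), " isolated electrode(s) at max_dist = ", max_dist,
            "; they can only form singleton clusters")
  structure(list(matrix = A,
                 neighbors = lapply(seq_len(nrow(A)), function(i) which(A[i, ])),
                 labels = montage$label,
                 max_dist = max_dist,
                 mean_degree = mean(deg)),
            class = "adjacency_graph")
}

#' Flatten a participants x channels x time array to participants x points
#' @noRd
flatten_diffs <- function(diffs) {
  d <- dim(diffs)
  matrix(diffs, d[1], d[2] * d[3])
}

#' Large finite sentinel used for zero-variance cells
#' @noRd
.t_sentinel <- 1e6

#' Row of t statistics for sign-flipped difference data
#'
#' X is participants x points; S is permutations x participants (+/-1).
#' Exploits that sign flips leave sum(x^2) unchanged.
#' @noRd
perm_t_rows <- function(S, X, css, n) {
  M <- (S %*% X) / n
  V <- (matrix(css, nrow(S), length(css), byrow = TRUE) - n * M^2) / (n - 1)
  T <- M / sqrt(V / n)
  bad <- !is.finite(T)
  if (any(bad)) T[bad] <- sign(M[bad]) * .t_sentinel
  T
}

#' Pointwise one-sample t-map of difference waveforms
#'
#' One-sample t against zero at every (channel, time) cell, df = n - 1.
#' Zero-variance cells are guarded to a large finite sentinel (sign of the
#' mean; 0 when the mean is 0 too) and reported via message.
#'
#' @param diffs participants x channels x time array of walking-minus-sitting
#'   mean-difference waveforms (microvolts)
#' @return channels x time matrix of t statistics
#' @export
pointwise_t <- function(diffs) {
  d <- dim(diffs)
  if (length(d) != 3 || d[1] < 3)
    stop_mobidt("invalid_config", "need a participants x channels x time array with n >= 3")
  X <- flatten_diffs(diffs)
  n <- d[1]
  css <- colSums(X^2)
  T <- perm_t_rows(matrix(1, 1, n), X, css, n)
  nz <- sum(abs(T) >= .t_sentinel)
  if (nz > 0) message(nz, " zero-variance cell(s) set to sentinel t values")
  matrix(T, d[2], d[3])
}

#' Form signed supra-threshold clusters and weighted masses
#'
#' Supra-threshold points (t > +`t_thresh` or t < -`t_thresh`) are linked
#' when they share an electrode at consecutive timepoints or are neighboring
#' electrodes at the same timepoint; clusters are sign-homogeneous. The
#' weighted cluster mass is `sum((|t| - t_thresh)^wcm_weight)` over members.
#'
#' @param t_map channels x time t matrix
#' @param adjacency an [build_adjacency()] graph
#' @param t_thresh positive cluster-forming threshold
#' @param wcm_weight exceedance exponent (default 1: exceedance-sum mass)
#' @return list of clusters, each with `members` (two-column matrix of
#'   channel/time indices), `sign`, `mass`; empty list when nothing is
#'   supra-threshold
#' @export
form_clusters <- function(t_map, adjacency, t_thresh, wcm_weight = 1) {
  if (t_thresh <= 0)
    stop_mobidt("invalid_config", "t_thresh must be positive")
  res <- label_clusters_cpp(t_map, adjacency$neighbors, t_thresh, wcm_weight)
  n_cl <- length(res$mass)
  if (n_cl == 0) return(list())
  lapply(seq_len(n_cl), function(k) {
    idx <- which(res$labels == k, arr.ind = TRUE)
    colnames(idx) <- c("channel", "time")
    list(members = idx, sign = res$sign[k], mass = res$mass[k])
  })
}

#' Cluster-based permutation test on difference waveforms
#'
#' The null is built by random sign flips of each participant's difference
#' waveform (valid under paired-design exchangeability). Per permutation the
#' maximum cluster mass per sign is recorded; each observed cluster's p-value
#' is `(1 + #[perm max >= observed]) / (1 + n_perm)` against the same-sign
#' null, doubled for two-sidedness and capped at 1. The cluster-forming
#' threshold is the two-tailed parametric t quantile at `alpha` with
#' df = n - 1.
#'
#' @param diffs participants x channels x time array (n >= 5 recommended)
#' @param adjacency [build_adjacency()] graph
#' @param n_perm number of Monte Carlo permutations (default 5000)
#' @param alpha significance level (cluster-forming and reporting)
#' @param seed optional RNG seed (fixed seed = reproducible p-values)
#' @param wcm_weight weighted-cluster-mass exponent (default 1)
#' @return list of class `cluster_result`: `t_map`, `t_thresh`, `clusters`
#'   (each with members/sign/mass/p_perm), `max_mass_null` (n_perm x 2),
#'   `n_permutations`, `alpha`, `any_significant`
#' @export
cluster_permutation_test <- function(diffs, adjacency, n_perm = 5000,
                                     alpha = 0.05, seed = NULL,
                                     wcm_weight = 1) {
  d <- dim(diffs)
  n <- d[1]
  if (n < 3)
    stop_mobidt("invalid_config", "need at least 3 participants")
  if (n_perm < 100)
    warning("fewer than 100 permutations gives a very coarse p-value grid")
  t_thresh <- qt(1 - alpha / 2, df = n - 1)
  X <- flatten_diffs(diffs)
  css <- colSums(X^2)
  t_obs <- perm_t_rows(matrix(1, 1, n), X, css, n)
  t_map <- matrix(t_obs, d[2], d[3])
  clusters <- form_clusters(t_map, adjacency, t_thresh, wcm_weight)
  null_max <- matrix(0, n_perm, 2)
  with_seed(seed, {
    chunk <- max(1L, min(n_perm, floor(2e7 / length(css))))
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
      Tp <- perm_t_rows(S, X, css, n)
      for (i in seq_len(nb))
        null_max[done + i, ] <- max_cluster_mass_cpp(Tp[i, ], d[2], d[3],
                                                     adjacency$neighbors,
                                                     t_thresh, wcm_weight)
      done <- done + nb
    }
  })
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    null_same <- if (cl$sign > 0) null_max[, 1] else null_max[, 2]
    p1 <- (1 + sum(null_same >= cl$mass)) / (1 + n_perm)
    clusters[[k]]$p_perm <- min(1, 2 * p1)
  }
  structure(list(t_map = t_map, t_thresh = t_thresh, clusters = clusters,
                 max_mass_null = null_max, n_permutations = n_perm,
                 alpha = alpha, wcm_weight = wcm_weight,
                 any_significant = any(vapply(clusters, function(cl)
                   cl$p_perm <= alpha, TRUE))),
            class = "cluster_result")
}

#' Minimum cluster p-value of a comparison (NA when no cluster formed)
#' @param result a `cluster_result`
#' @return smallest permutation p-value, or NA
#' @export
min_cluster_p <- function(result) {
  if (length(result$clusters) == 0) return(NA_real_)
  min(vapply(result$clusters, `[[`, 0, "p_perm"))
}

#' Within-participant walking-minus-sitting difference waveforms
#'
#' @param sitting,walking lists of `erp_waveform` objects (one per
#'   participant, matching order and geometry)
#' @return participants x channels x time array
#' @export
diff_waves <- function(sitting, walking) {
  if (length(sitting) != length(walking) || length(sitting) == 0)
    stop_mobidt("invalid_config", "need matching non-empty waveform lists")
  d <- dim(sitting[[1]]$data)
  out <- array(0, c(length(sitting), d[1], d[2]))
  for (i in seq_along(sitting))
    out[i, , ] <- walking[[i]]$data - sitting[[i]]$data
  out
}
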
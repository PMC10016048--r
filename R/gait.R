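# Gait-cycle segmentation and stride-to-stride variability via dynamic time
# warping. Heel strikes are local maxima of the fore-aft (Z) heel position
# with topographic prominence above 0.1 m; a gait cycle is the interval
# between two consecutive strikes of the same foot; cycles are resampled to
# 100 points and compared consecutive-versus-next with DTW (3D Euclidean
# local cost); left- and right-foot distances are pooled into one mean.

#' Detect heel strikes as prominent local maxima of the Z position
#'
#' Topographic prominence of a peak: walk outward in both directions until a
#' higher sample (or the series end) is met; the prominence is the peak height
#' minus the higher of the two intervening minima. Only peaks with prominence
#' strictly greater than `min_prominence_m` are kept.
#'
#' @param z fore-aft position series, meters (length >= 3)
#' @param min_prominence_m prominence cutoff in meters (default 0.1)
#' @return strictly increasing sample indices of accepted peaks (possibly
#'   empty)
#' @export
detect_heel_strikes <- function(z, min_prominence_m = 0.1) {
  n <- length(z)
  if (n < 3)
    stop_mobidt("invalid_config", "series must have at least 3 samples")
  is_peak <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] > z[3:n]) + 1L
  keep <- logical(length(is_peak))
  for (k in seq_along(is_peak)) {
    i <- is_peak[k]
    h <- z[i]
    # left side
    j <- i - 1
    lmin <- h
    while (j >= 1 && z[j] < h) {
      if (z[j] < lmin) lmin <- z[j]
      j <- j - 1
    }
    # right side
    j <- i + 1
    rmin <- h
    while (j <= n && z[j] < h) {
      if (z[j] < rmin) rmin <- z[j]
      j <- j + 1
    }
    keep[k] <- (h - max(lmin, rmin)) > min_prominence_m
  }
  is_peak[keep]
}

#' Segment a trace into gait cycles
#'
#' Cycle k covers samples `[strike_k, strike_{k+1})`.
#'
#' @param trace a `gait_trace` (see [gen_gait_trace()]) or any list with an
#'   `xyz` samples x 3 matrix and a `foot` label
#' @param strikes strictly increasing strike sample indices (>= 2)
#' @return list of `gait_cycle` lists: `foot`, `start_idx`, `end_idx`
#'   (exclusive), `samples` (raw n x 3 matrix)
#' @export
segment_cycles <- function(trace, strikes) {
  if (length(strikes) < 2)
    stop_mobidt("no_cycles", "need at least 2 heel strikes to form a cycle")
  lapply(seq_len(length(strikes) - 1), function(k) {
    idx <- strikes[k]:(strikes[k + 1] - 1L)
    structure(list(foot = trace$foot %||% NA_character_,
                   start_idx = strikes[k], end_idx = strikes[k + 1],
                   samples = trace$xyz[idx, , drop = FALSE]),
              class = "gait_cycle")
  })
}

#' Reject outlier cycles by kurtosis
#'
#' Each cycle's statistic is the maximum over the three coordinates of the
#' sample kurtosis of that coordinate's trajectory; cycles whose statistic
#' deviates from the across-cycle mean by more than `k_sd` standard
#' deviations are removed. A zero SD (e.g. identical cycles) rejects nothing.
#'
#' @param cycles list of cycles (raw or resampled; anything with `samples` or
#'   a plain n x 3 matrix per element)
#' @param k_sd SD threshold (default 5); `Inf` is the identity
#' @return list with `kept` (cycles), `rejected` (indices)
#' @export
reject_outlier_cycles <- function(cycles, k_sd = 5) {
  if (length(cycles) < 3)
    stop_mobidt("invalid_config", "need at least 3 cycles for outlier statistics")
  stat <- vapply(cycles, function(cy) {
    m <- if (is.list(cy)) cy$samples else cy
    ks <- apply(m, 2, kurtosis_moment)
    max(ks[is.finite(ks)], -Inf)
  }, 0)
  z <- guarded_z(stat)
  rejected <- which(is.finite(k_sd) & abs(z) > k_sd)
  if (length(rejected) == length(cycles))
    stop_mobidt("degenerate_set", "all cycles rejected as outliers")
  list(kept = cycles[setdiff(seq_along(cycles), rejected)],
       rejected = rejected)
}

#' Resample a cycle trajectory to a fixed number of phase points
#'
#' Linear interpolation of each coordinate onto `n` evenly spaced points over
#' the cycle; endpoints are preserved.
#'
#' @param cycle a `gait_cycle` or an m x 3 matrix (m >= 2)
#' @param n number of output samples (default 100)
#' @return n x 3 matrix
#' @export
resample_cycle <- function(cycle, n = 100) {
  if (n < 2) stop_mobidt("invalid_config", "resampling needs n >= 2")
  m <- if (is.list(cycle)) cycle$samples else cycle
  len <- nrow(m)
  if (len < 2) stop_mobidt("invalid_config", "cycle must have >= 2 samples")
  phase_in <- seq(0, 1, length.out = len)
  phase_out <- seq(0, 1, length.out = n)
  apply(m, 2, function(col) approx(phase_in, col, xout = phase_out)$y)
}

#' Dynamic time warping distance between two 3D trajectories
#'
#' Classical DTW with 3D Euclidean local cost, symmetric step pattern
#' (match/insert/delete), no warping window, boundary-anchored; returns the
#' unnormalized minimal cumulative cost in meters.
#'
#' @param a,b m x 3 and n x 3 trajectories
#' @return DTW distance (>= 0; 0 iff the trajectories are identical)
#' @export
#' @examples
#' dtw_distance(matrix(0, 1, 3), matrix(c(3, 4, 0), 1, 3))  # 5
dtw_distance <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != 3 || ncol(b) != 3)
    stop_mobidt("shape", "trajectories must be m x 3 matrices")
  dtw_dist_cpp(a, b)
}

#' Pooled mean stride-to-stride DTW distance
#'
#' DTW is computed between consecutive kept cycles within each foot (cycle i
#' versus i + 1); left- and right-foot distances are pooled and averaged.
#'
#' @param cycles_left,cycles_right lists of resampled cycle trajectories
#'   (n x 3 matrices or `gait_cycle`-like lists); either may be empty
#' @return list: `mean_dtw_m`, `distances` (pooled vector), `n_comparisons`
#' @export
mean_dtw <- function(cycles_left, cycles_right = list()) {
  as_mat <- function(cy) if (is.list(cy) && !is.null(cy$samples)) cy$samples else cy
  consec <- function(cycles) {
    if (length(cycles) < 2) return(numeric(0))
    vapply(seq_len(length(cycles) - 1), function(i)
      dtw_distance(as_mat(cycles[[i]]), as_mat(cycles[[i + 1]])), 0)
  }
  d <- c(consec(cycles_left), consec(cycles_right))
  if (length(d) == 0)
    stop_mobidt("empty_sample", "no consecutive cycle pair to compare")
  list(mean_dtw_m = mean(d), distances = d, n_comparisons = length(d))
}

#' Full gait-variability summary for one participant-condition
#'
#' Chains strike detection, segmentation, pooled outlier rejection (left and
#' right cycles share one kurtosis mean/SD), resampling and pooled mean DTW.
#'
#' @param trace_left,trace_right `gait_trace` objects for the two feet
#' @param min_prominence_m strike prominence cutoff (default 0.1 m)
#' @param n_resample points per resampled cycle (default 100)
#' @param k_sd cycle outlier threshold in SDs (default 5)
#' @return data.frame row: `n_cycles_kept`, `n_cycles_rejected`, `mean_dtw_m`
#' @export
gait_summary <- function(trace_left, trace_right,
                         min_prominence_m = 0.1, n_resample = 100, k_sd = 5) {
  cycles_of <- function(trace) {
    strikes <- detect_heel_strikes(trace$xyz[, 3], min_prominence_m)
    segment_cycles(trace, strikes)
  }
  cl <- cycles_of(trace_left)
  cr <- cycles_of(trace_right)
  pooled <- reject_outlier_cycles(c(cl, cr), k_sd)
  nl <- length(cl)
  keep_idx <- setdiff(seq_len(nl + length(cr)), pooled$rejected)
  left_kept <- lapply(cl[intersect(keep_idx, seq_len(nl))],
                      resample_cycle, n = n_resample)
  right_kept <- lapply(cr[intersect(keep_idx, nl + seq_along(cr)) - nl],
                       resample_cycle, n = n_resample)
  md <- mean_dtw(left_kept, right_kept)
  data.frame(n_cycles_kept = length(left_kept) + length(right_kept),
             n_cycles_rejected = length(pooled$rejected),
             mean_dtw_m = md$mean_dtw_m)
}
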
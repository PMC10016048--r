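# Independent oracles used across the suite.

# Exhaustive DTW: explicit depth-first enumeration of every admissible
# boundary-anchored monotone warping path (steps down/right/diagonal),
# returning the minimal summed Euclidean cost. Exponential; use only for
# trajectories of length <= 6.
dtw_exhaustive <- function(a, b) {
  m <- nrow(a)
  n <- nrow(b)
  dloc <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + dloc(i, j)
    if (acc >= best) return(invisible())
    if (i == m && j == n) {
      best <<- acc
      return(invisible())
    }
    if (i < m) walk(i + 1, j, acc)
    if (j < n) walk(i, j + 1, acc)
    if (i < m && j < n) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign patterns over the observed absolute-difference ranks (no zeros
# assumed). Returns P(|W+ - mu| >= |w_obs - mu|).
wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  pats <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(pats) %*% r
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# Two-stage step-up FDR reference cases, computed once with an independent
# implementation (statsmodels fdr_tsbky) and frozen here.
bky_reference_cases <- list(
  list(p = c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216),
       rej = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
  list(p = c(0.128114, 0.004389, 0.975622, 0.006974, 0.094177, 0.76114,
             0.008586, 0.450386, 0.786064),
       rej = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)),
  list(p = c(0.970698, 0.758088, 0.893121, 0.631664, 0.778383, 0.008276,
             0.354526, 0.000638),
       rej = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)),
  list(p = c(0.669814, 0.189471, 0.832678, 0.004696, 0.437152, 0.003705,
             0.003258, 0.226909, 0.312367, 0.700265, 0.129922, 0.475705),
       rej = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
               FALSE, FALSE, FALSE)),
  list(p = c(0.786924, 0.553579, 0.634718, 0.568741, 0.664851, 0.458916,
             0.471096, 0.139797, 0.668403, 0.11453, 0.705165, 0.565236,
             0.780729, 0.764999),
       rej = rep(FALSE, 14))
)

# Small shared fixtures
test_montage <- montage_biosemi64()
test_adjacency <- build_adjacency(test_montage, 0.45)

# Random 3D trajectory of given length
rand_traj <- function(n) matrix(rnorm(n * 3), n, 3)
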
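# Scalar statistics: normality-gated paired tests, Wilcoxon signed rank with
# a normal-approximation z, independent t, mixed 2x2 ANOVA with classical
# eta-squared, improver classification against a cohort null, and the
# two-stage step-up FDR with the combined p-value set.

#' Route a paired comparison to a parametric or nonparametric test
#'
#' Shapiro-Wilk on the paired differences at level `alpha`: parametric when
#' normality is not rejected, nonparametric otherwise. A constant sample is
#' routed nonparametric with a warning.
#'
#' @param differences numeric vector of paired differences (n >= 3)
#' @param alpha normality test level (default 0.05)
#' @return "parametric" or "nonparametric", with the Shapiro p-value as
#'   attribute `shapiro_p`
#' @export
normality_gate <- function(differences, alpha = 0.05) {
  if (length(differences) < 3)
    stop_mobidt("invalid_config", "need at least 3 differences")
  if (sd(differences) == 0) {
    warning("constant differences; routing to the nonparametric branch")
    return(structure("nonparametric", shapiro_p = NA_real_))
  }
  p <- shapiro.test(differences)$p.value
  structure(if (p > alpha) "parametric" else "nonparametric", shapiro_p = p)
}

#' @noRd
test_result <- function(test, statistic, df, p_value, effect_size,
                        effect_type, tails = 2) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 effect_type = effect_type, tails = tails),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g, %s = %.3g\n",
              x$test, x$statistic, paste(round(x$df, 2), collapse = ","),
              x$p_value, x$effect_type, x$effect_size))
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' `t = mean(x - y) / (sd(x - y) / sqrt(n))`, df = n - 1, two-tailed p;
#' Cohen's d = mean difference / SD of differences = t / sqrt(n).
#'
#' @param x,y paired samples of equal length (n >= 2)
#' @return a `test_result`
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_mobidt("invalid_config", "paired samples must have equal length >= 2")
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (s == 0) stop_mobidt("degenerate", "zero-variance differences")
  t <- mean(d) / (s / sqrt(n))
  test_result("paired_t", t, n - 1, 2 * pt(-abs(t), n - 1),
              t / sqrt(n), "cohens_d")
}

#' Wilcoxon signed rank test with normal-approximation z and Cohen's r
#'
#' Zero differences are dropped; ties receive average ranks. The z statistic
#' uses the normal approximation with tie and continuity corrections; the
#' two-tailed p comes from that z. Cohen's r = |z| / sqrt(N) with N = 2n
#' observations across both conditions (n = original pairs).
#'
#' @param x,y paired samples (n >= 5 recommended for the approximation)
#' @return a `test_result` (statistic = z; `df` = NA)
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y))
    stop_mobidt("invalid_config", "paired samples must have equal length")
  n_pairs <- length(x)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_mobidt("degenerate", "all differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) stop_mobidt("degenerate", "degenerate rank variance")
  cc <- if (w_pos != mu) 0.5 * sign(w_pos - mu) else 0
  z <- (w_pos - mu - cc) / sqrt(sigma2)
  test_result("wilcoxon_signed_rank", z, NA_real_, 2 * pnorm(-abs(z)),
              abs(z) / sqrt(2 * n_pairs), "cohens_r")
}

#' Independent-samples t-test (pooled variance) with Cohen's d
#'
#' @param a,b samples (each n >= 2)
#' @return a `test_result` with df = n1 + n2 - 2
#' @export
independent_t <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2 || n2 < 2)
    stop_mobidt("invalid_config", "each group needs n >= 2")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop_mobidt("degenerate", "zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  test_result("independent_t", t, n1 + n2 - 2, 2 * pt(-abs(t), n1 + n2 - 2),
              (mean(a) - mean(b)) / sqrt(sp2), "cohens_d")
}

#' Mixed 2x2 ANOVA (one between-subject, one within-subject factor)
#'
#' Classical univariate mixed-design decomposition: the between factor is
#' tested against the subject-within-group error, the within factor and the
#' interaction against the subject x within error. Effect sizes are classical
#' eta-squared (effect SS / total SS). The sums of squares satisfy
#' SS_total = sum of effect SS + sum of error SS.
#'
#' @param group factor/character vector of group labels, one per subject
#'   (exactly 2 levels, each with n >= 2)
#' @param y subjects x 2 matrix of the repeated measures (within levels in
#'   columns)
#' @return list with `group`, `within`, `interaction` (`test_result`s with
#'   eta-squared) and an `ss` table
#' @export
anova_2x2_mixed <- function(group, y) {
  y <- as.matrix(y)
  if (ncol(y) != 2) stop_mobidt("invalid_config", "y must have 2 within levels")
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) < 2))
    stop_mobidt("invalid_config", "need 2 groups with n >= 2 each")
  if (anyNA(y)) stop_mobidt("invalid_config", "missing cells are not supported")
  n_s <- nrow(y)
  gmean <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, group, mean)
  n_g <- table(group)
  ss_group <- 2 * sum(n_g * (grp_mean - gmean)^2)
  ss_subj <- 2 * sum((subj_mean - grp_mean[group])^2)
  half_diff <- (y[, 2] - y[, 1]) / 2           # within-subject deviation
  dbar <- mean(half_diff)
  dbar_g <- tapply(half_diff, group, mean)
  ss_within_f <- 2 * n_s * dbar^2
  ss_inter <- 2 * sum(n_g * (dbar_g - dbar)^2)
  ss_err_w <- 2 * sum((half_diff - dbar_g[group])^2)
  ss_total <- sum((y - gmean)^2)
  df_err_b <- n_s - 2
  df_err_w <- n_s - 2
  f_of <- function(ss_eff, ss_err, df_err) {
    if (ss_err == 0) stop_mobidt("degenerate", "zero error sum of squares")
    f <- (ss_eff / 1) / (ss_err / df_err)
    list(f = f, p = stats::pf(f, 1, df_err, lower.tail = FALSE))
  }
  g <- f_of(ss_group, ss_subj, df_err_b)
  w <- f_of(ss_within_f, ss_err_w, df_err_w)
  i <- f_of(ss_inter, ss_err_w, df_err_w)
  eta <- function(ss) ss / ss_total
  list(group = test_result("anova_group", g$f, c(1, df_err_b), g$p,
                           eta(ss_group), "eta_squared"),
       within = test_result("anova_within", w$f, c(1, df_err_w), w$p,
                            eta(ss_within_f), "eta_squared"),
       interaction = test_result("anova_interaction", i$f, c(1, df_err_w),
                                 i$p, eta(ss_inter), "eta_squared"),
       ss = c(group = ss_group, subj_within_group = ss_subj,
              within = ss_within_f, interaction = ss_inter,
              error_within = ss_err_w, total = ss_total))
}

#' Classify a participant as improver (IMP) or non-improver (nIMP)
#'
#' The null is a normal distribution with mean zero and SD equal to the
#' sample SD (n - 1 denominator) of the whole cohort's walking-minus-sitting
#' d' differences (the candidate included). The 95% bound is
#' `qnorm(1 - alpha/2) * SD`; only a positive exceedance maps to IMP —
#' significant decliners and no-change participants are nIMP.
#'
#' @param delta_dprime the participant's walking-minus-sitting d' difference
#' @param cohort_deltas all participants' differences (length >= 3)
#' @param alpha two-sided CI level (default 0.05)
#' @return "IMP" or "nIMP", with attribute `threshold`
#' @export
classify_improver <- function(delta_dprime, cohort_deltas, alpha = 0.05) {
  if (length(cohort_deltas) < 3)
    stop_mobidt("invalid_config", "cohort must have at least 3 participants")
  sigma <- sd(cohort_deltas)
  if (sigma == 0)
    stop_mobidt("degenerate", "degenerate cohort: zero SD of differences")
  thr <- qnorm(1 - alpha / 2) * sigma
  structure(if (delta_dprime > thr) "IMP" else "nIMP", threshold = thr)
}

#' Two-stage step-up FDR (Benjamini-Krieger-Yekutieli)
#'
#' Stage 1 runs Benjamini-Hochberg at `q' = q / (1 + q)` to estimate the
#' number of true nulls `m0 = m - r1`; stage 2 reruns the step-up at the
#' sharpened level `q' * m / m0`. Rejects a superset of plain BH at the same
#' `q`.
#'
#' @param p vector of p-values in (0, 1]
#' @param q target false discovery rate (default 0.05)
#' @return list: `reject` (logical mask, input order), `critical_p` (largest
#'   rejected p; NA when none), `m0_estimate`
#' @export
bky_fdr <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0) return(list(reject = logical(0), critical_p = NA_real_,
                          m0_estimate = 0L))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_mobidt("invalid_config", "p-values must lie in (0, 1]")
  bh <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    ok <- p[o] <= thr
    k <- if (any(ok)) max(which(ok)) else 0L
    rej <- logical(m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  r1 <- sum(bh(p, q1))
  if (r1 == 0)
    return(list(reject = logical(m), critical_p = NA_real_, m0_estimate = m))
  if (r1 == m)
    return(list(reject = rep(TRUE, m), critical_p = max(p), m0_estimate = 0L))
  m0 <- m - r1
  rej <- bh(p, q1 * m / m0)
  list(reject = rej,
       critical_p = if (any(rej)) max(p[rej]) else NA_real_,
       m0_estimate = m0)
}

#' Assemble the combined p-value set for FDR control
#'
#' Union of all scalar-test p-values (one per paired/independent test, three
#' per 2x2 ANOVA) and, for each EEG comparison, the minimum cluster p-value
#' when at least one cluster formed (a comparison without clusters
#' contributes nothing). The order of entries is recorded for audit.
#'
#' @param scalar_results named list of `test_result` objects (ANOVAs appear
#'   as their three component results)
#' @param cluster_results named list of `cluster_result` objects
#' @return data.frame with `source` and `p` columns, in audit order
#' @export
aggregate_pvalues_for_fdr <- function(scalar_results = list(),
                                      cluster_results = list()) {
  rows <- list()
  for (nm in names(scalar_results)) {
    r <- scalar_results[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(source = nm, p = r$p_value)
  }
  for (nm in names(cluster_results)) {
    p <- min_cluster_p(cluster_results[[nm]])
    if (!is.na(p))
      rows[[length(rows) + 1L]] <- data.frame(source = paste0("eeg:", nm), p = p)
  }
  if (length(rows) == 0)
    return(data.frame(source = character(0), p = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
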
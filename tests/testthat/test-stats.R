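test_that("the normality gate routes parametric vs nonparametric sensibly", {
  set.seed(51)
  par_n <- sum(vapply(1:100, function(i)
    normality_gate(rnorm(26)) == "parametric", TRUE))
  expect_gte(par_n, 85)                        # ~95% under normal draws
  np_n <- sum(vapply(1:50, function(i)
    normality_gate(stats::rcauchy(25)) == "nonparametric", TRUE))
  expect_gte(np_n, 45)                         # >= 90% under heavy tails
  expect_warning(g <- normality_gate(rep(1, 10)), "constant")
  expect_equal(as.character(g), "nonparametric")
  expect_error(normality_gate(c(1, 2)), class = "invalid_config")
})

test_that("paired t matches the formula oracle and the d = t/sqrt(n) identity", {
  set.seed(52)
  x <- rnorm(15, 1)
  y <- rnorm(15)
  r <- paired_t(x, y)
  d <- x - y
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(15)), tolerance = 1e-12)
  expect_equal(r$df, 14)
  expect_equal(r$p_value, stats::t.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(r$effect_size, r$statistic / sqrt(15), tolerance = 1e-12)
  expect_error(paired_t(x, x), class = "degenerate")
  expect_error(paired_t(1:3, 1:4), class = "invalid_config")
})

test_that("Wilcoxon z agrees with the enumeration oracle and wilcox.test", {
  set.seed(53)
  for (k in 1:5) {
    x <- rnorm(8, 0.8)
    y <- rnorm(8)
    r <- wilcoxon_signed_rank(x, y)
    p_exact <- wilcoxon_exact_p(x - y)
    expect_lt(abs(r$p_value - p_exact), 0.05)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               correct = TRUE, exact = FALSE))
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
  }
  # antisymmetric sample: z ~ 0
  d <- c(-3, -2, -1, 1, 2, 3)
  rz <- wilcoxon_signed_rank(d, rep(0, 6))
  expect_lt(abs(rz$statistic), 0.2)
  expect_error(wilcoxon_signed_rank(rep(1, 5), rep(1, 5)), class = "degenerate")
})

test_that("independent t matches the pooled-variance oracle", {
  set.seed(54)
  a <- rnorm(14, 1)
  b <- rnorm(12)
  r <- independent_t(a, b)
  sp2 <- ((13) * var(a) + (11) * var(b)) / 24
  expect_equal(r$statistic, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 14 + 1 / 12)),
               tolerance = 1e-12)
  expect_equal(r$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(independent_t(a, a)$statistic, 0)
  expect_gt(independent_t(a + 5, b)$statistic, 0)
  expect_lt(independent_t(a - 5, b)$statistic, 0)
  expect_error(independent_t(rep(1, 3), rep(1, 4)), class = "degenerate")
})

test_that("the mixed 2x2 ANOVA matches aov and conserves sums of squares", {
  set.seed(55)
  for (k in 1:3) {
    n1 <- 13
    n2 <- 12
    grp <- rep(c("IMP", "nIMP"), c(n1, n2))
    y <- cbind(rnorm(n1 + n2, ifelse(grp == "IMP", 10, 12)),
               rnorm(n1 + n2, ifelse(grp == "IMP", 11, 12.5)))
    r <- anova_2x2_mixed(grp, y)
    # aov oracle (univariate mixed model, Type I)
    df <- data.frame(y = c(y[, 1], y[, 2]),
                     load = rep(c("A", "B"), each = n1 + n2),
                     grp = rep(grp, 2), subj = factor(rep(seq_len(n1 + n2), 2)))
    fit <- summary(stats::aov(y ~ grp * load + Error(subj / load), data = df))
    between <- fit[["Error: subj"]][[1]]
    within <- fit[["Error: subj:load"]][[1]]
    expect_equal(r$group$statistic, between["grp", "F value"], tolerance = 1e-8)
    expect_equal(r$group$p_value, between["grp", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(r$within$statistic, within["load", "F value"], tolerance = 1e-8)
    expect_equal(r$interaction$statistic, within["grp:load", "F value"],
                 tolerance = 1e-8)
    # SS conservation to 1e-9 relative
    ss <- r$ss
    expect_equal(ss[["total"]],
                 ss[["group"]] + ss[["subj_within_group"]] + ss[["within"]] +
                   ss[["interaction"]] + ss[["error_within"]],
                 tolerance = 1e-9)
    # eta-squared = effect SS / total SS
    expect_equal(r$group$effect_size, ss[["group"]] / ss[["total"]])
  }
  # all observations equal: F undefined (zero error SS)
  expect_error(anova_2x2_mixed(rep(c("a", "b"), 3), matrix(5, 6, 2)),
               class = "degenerate")
  expect_error(anova_2x2_mixed(rep("a", 4), matrix(rnorm(8), 4, 2)),
               class = "invalid_config")
})

test_that("ANOVA power: injected group effect detected, absent load effect not", {
  set.seed(56)
  hit_g <- 0
  miss_l <- 0
  for (k in 1:100) {
    grp <- rep(c("IMP", "nIMP"), c(13, 12))
    base <- rnorm(25, ifelse(grp == "IMP", 0, 1.8))  # group effect only
    y <- cbind(base + rnorm(25, 0, 0.5), base + rnorm(25, 0, 0.5))
    r <- anova_2x2_mixed(grp, y)
    if (r$group$p_value < 0.05) hit_g <- hit_g + 1
    if (r$within$p_value > 0.2) miss_l <- miss_l + 1
  }
  expect_gte(hit_g, 90)
  expect_gte(miss_l, 70)
})

test_that("improver classification thresholds at the cohort-null 95% bound", {
  deltas <- c(rep(0.1, 20), rnorm(6, 0, 0.6))
  sigma <- sd(deltas)
  thr <- qnorm(0.975) * sigma
  r <- classify_improver(1.5 * thr, deltas)
  expect_equal(as.character(r), "IMP")
  expect_equal(attr(r, "threshold"), thr)
  expect_equal(as.character(classify_improver(0, deltas)), "nIMP")
  # significant decline still maps to nIMP
  expect_equal(as.character(classify_improver(-10 * thr, deltas)), "nIMP")
  # normal-quantile oracle: sd 0.4 -> threshold 0.784
  set.seed(57)
  d2 <- rnorm(400)
  d2 <- (d2 - mean(d2)) / sd(d2) * 0.4
  expect_equal(as.character(classify_improver(1.0, d2)), "IMP")     # > 0.784
  expect_equal(as.character(classify_improver(0.7, d2)), "nIMP")
  expect_equal(as.character(classify_improver(-1.0, d2)), "nIMP")
  expect_error(classify_improver(1, rep(0, 5)), class = "degenerate")
  expect_error(classify_improver(1, c(0, 1)), class = "invalid_config")
})

test_that("two-stage FDR matches the frozen reference and dominates BH", {
  for (case in bky_reference_cases) {
    r <- bky_fdr(case$p, q = 0.05)
    expect_equal(r$reject, case$rej)
  }
  # trivial extremes
  expect_false(any(bky_fdr(rep(0.9, 16))$reject))
  expect_true(all(bky_fdr(rep(0.001, 16))$reject))
  expect_length(bky_fdr(numeric(0))$reject, 0)
  # superset-of-BH property on random vectors
  set.seed(58)
  for (k in 1:50) {
    p <- c(runif(sample(3:12, 1)), runif(sample(0:4, 1), 0, 0.01))
    bh <- stats::p.adjust(p, "BH") <= 0.05
    bky <- bky_fdr(p, 0.05)$reject
    expect_true(all(bky[bh]))                  # BKY rejects everything BH does
  }
  expect_error(bky_fdr(c(0.5, 0)), class = "invalid_config")
})

test_that("the FDR p-value set assembles scalar and minimum cluster p-values", {
  tr <- function(p) structure(list(p_value = p), class = "test_result")
  cl_with <- structure(list(clusters = list(list(p_perm = 0.01),
                                            list(p_perm = 0.2))),
                       class = "cluster_result")
  cl_none <- structure(list(clusters = list()), class = "cluster_result")
  out <- aggregate_pvalues_for_fdr(list(a = tr(0.3), b = tr(0.04)),
                                   list(cmpA = cl_with, cmpB = cl_none))
  expect_equal(nrow(out), 3)                   # comparison without clusters: nothing
  expect_equal(out$p, c(0.3, 0.04, 0.01))
  expect_equal(out$source, c("a", "b", "eeg:cmpA"))
  single <- aggregate_pvalues_for_fdr(list(only = tr(0.5)), list())
  expect_equal(nrow(single), 1)
})
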
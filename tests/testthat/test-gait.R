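test_that("heel strikes are prominent local maxima of the Z series", {
  # 0.3-m amplitude sinusoid at the stride period: every cycle's argmax
  t <- seq(0, 10, by = 1 / 360)
  z <- 0.3 * sin(2 * pi * t / 1.1)
  strikes <- detect_heel_strikes(z)
  # brute-force per-period argmax oracle
  per <- floor(t / 1.1)
  oracle <- vapply(unique(per), function(k) {
    idx <- which(per == k)
    idx[which.max(z[idx])]
  }, 0L)
  oracle <- oracle[z[oracle] > 0.25]           # interior true peaks only
  expect_true(all(strikes %in% oracle) && all(oracle %in% strikes))
  # constant series: nothing
  expect_length(detect_heel_strikes(rep(1, 100)), 0)
  # prominence gate: 0.04-m amplitude => prominence 0.08 < 0.1
  z2 <- 0.04 * sin(2 * pi * t / 1.1)
  expect_length(detect_heel_strikes(z2), 0)
  # ... but passes a lower cutoff
  expect_gt(length(detect_heel_strikes(z2, 0.05)), 5)
  expect_error(detect_heel_strikes(c(1, 2)), class = "invalid_config")
})

test_that("cycle segmentation covers [first, last) without gaps", {
  tr <- list(foot = "left", xyz = matrix(rnorm(3000), 1000, 3))
  cyc <- segment_cycles(tr, c(100, 496, 892))
  expect_length(cyc, 2)
  expect_equal(cyc[[1]]$start_idx, 100)
  expect_equal(cyc[[1]]$end_idx, 496)
  expect_equal(nrow(cyc[[1]]$samples), 396)
  covered <- unlist(lapply(cyc, function(c) c$start_idx:(c$end_idx - 1)))
  expect_equal(covered, 100:891)
  expect_error(segment_cycles(tr, 100), class = "no_cycles")
})

test_that("kurtosis-based outlier rejection removes exactly the corrupted cycle", {
  set.seed(5)
  base <- resample_cycle(gait_template_cycle <- matrix(
    c(sin(seq(0, 2 * pi, length.out = 120)),
      cos(seq(0, 2 * pi, length.out = 120)),
      seq(0, 1, length.out = 120)), 120, 3))
  cycles <- lapply(1:51, function(i) base + rnorm(300, 0, 0.01))
  spike <- cycles[[17]]
  spike[50, ] <- spike[50, ] + 25              # extreme-kurtosis spike
  cycles[[17]] <- spike
  r <- reject_outlier_cycles(cycles)
  expect_equal(r$rejected, 17L)
  expect_length(r$kept, 50)
  # identical cycles: SD = 0 guard keeps all
  same <- lapply(1:5, function(i) base)
  expect_length(reject_outlier_cycles(same)$rejected, 0)
  # infinite threshold is the identity
  expect_length(reject_outlier_cycles(cycles, k_sd = Inf)$rejected, 0)
  expect_error(reject_outlier_cycles(cycles[1:2]), class = "invalid_config")
})

test_that("resampling is linear-exact and analytically accurate", {
  ramp <- cbind(seq(0, 1, length.out = 50), seq(2, 4, length.out = 50),
                seq(-1, 1, length.out = 50))
  r <- resample_cycle(ramp, 100)
  expect_equal(dim(r), c(100, 3))
  expect_equal(r[1, ], ramp[1, ])              # endpoints preserved
  expect_equal(r[100, ], ramp[50, ])
  expect_equal(r[, 1], seq(0, 1, length.out = 100), tolerance = 1e-12)
  # already-100-sample cycle keeps endpoints
  m100 <- matrix(rnorm(300), 100, 3)
  r100 <- resample_cycle(m100, 100)
  expect_equal(r100, m100, tolerance = 1e-12)
  # 396-sample sine resampled to 100: near-analytic
  ph <- seq(0, 1, length.out = 396)
  sine <- cbind(sin(2 * pi * ph), cos(2 * pi * ph), 0 * ph)
  rs <- resample_cycle(sine, 100)
  ph2 <- seq(0, 1, length.out = 100)
  expect_lt(max(abs(rs[, 1] - sin(2 * pi * ph2))), 1e-3)
  expect_error(resample_cycle(ramp, 1), class = "invalid_config")
})

test_that("DTW matches hand values and the exhaustive-path oracle", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(dtw_distance(a, a), 0)
  expect_equal(dtw_distance(a, b), 5)
  A <- matrix(c(0, 1, 2, rep(0, 6)), 3, 3)
  B <- matrix(c(0, 2, rep(0, 4)), 2, 3)
  expect_equal(dtw_distance(A, B), 1)          # exhaustive DP hand value
  set.seed(11)
  for (k in 1:30) {
    x <- rand_traj(sample(1:6, 1))
    y <- rand_traj(sample(1:6, 1))
    expect_equal(dtw_distance(x, y), dtw_exhaustive(x, y), tolerance = 1e-10)
    expect_equal(dtw_distance(x, y), dtw_distance(y, x))
    expect_gte(dtw_distance(x, y), 0)
  }
  expect_error(dtw_distance(matrix(0, 2, 2), matrix(0, 2, 3)), class = "shape")
})

test_that("pooled mean DTW is translation-invariant and averages both feet", {
  set.seed(12)
  cl <- lapply(1:4, function(i) rand_traj(10))
  cr <- lapply(1:3, function(i) rand_traj(10))
  md <- mean_dtw(cl, cr)
  expect_equal(md$n_comparisons, 5)            # 3 left pairs + 2 right pairs
  expect_equal(md$mean_dtw_m, mean(md$distances))
  # constant offset applied to every cycle leaves all distances unchanged
  off <- matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  md2 <- mean_dtw(lapply(cl, `+`, off), lapply(cr, `+`, off))
  expect_equal(md2$distances, md$distances, tolerance = 1e-12)
  # identical cycles: 0
  expect_equal(mean_dtw(lapply(1:3, function(i) cl[[1]]))$mean_dtw_m, 0)
  expect_error(mean_dtw(list(cl[[1]])), class = "empty_sample")
})

test_that("the DT < ST jitter ordering propagates to recovered mean DTW", {
  md_of <- function(j, seed) {
    tl <- gen_gait_trace(30, 1.1, j, seed = seed, foot = "left")
    tr <- gen_gait_trace(30, 1.1, j, seed = seed + 500, foot = "right")
    gait_summary(tl, tr)$mean_dtw_m
  }
  wins <- sum(vapply(1:20, function(s) md_of(0.05, s) > md_of(0.01, s), TRUE))
  expect_gte(wins, 19)
})
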
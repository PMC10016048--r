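test_that("the zero-phase lowpass preserves DC and passband, kills the stopband", {
  fs <- 512
  t <- seq(0, 4, by = 1 / fs)
  band <- list(type = "low", edges_hz = c(45, 50), apass_db = 1, astop_db = 65)
  # pure DC unchanged
  dc <- cheby2_zero_phase(rep(3.3, 1500), fs, band)
  expect_lt(max(abs(dc - 3.3)), 1e-9)
  # 60-Hz sinusoid attenuated by at least 65 dB
  y60 <- cheby2_zero_phase(sin(2 * pi * 60 * t), fs, band)
  core <- y60[500:(length(y60) - 500)]
  expect_lt(20 * log10(max(abs(core))), -65)
  # 10-Hz passband within the 1-dB ripple
  y10 <- cheby2_zero_phase(sin(2 * pi * 10 * t), fs, band)
  expect_equal(max(abs(y10[500:(length(y10) - 500)])), 1, tolerance = 0.02)
  # impulse response symmetric (zero phase)
  x <- rep(0, 2001)
  x[1001] <- 1
  h <- cheby2_zero_phase(x, fs, band)
  expect_lt(max(abs(h - rev(h))), 1e-9)
  expect_error(cheby2_zero_phase(t, fs, list(type = "low", edges_hz = c(250, 300))),
               class = "filter_design")
})

test_that("downsampling decimates with anti-aliasing", {
  x <- rep(1, 2048)
  y <- downsample(x, 2048, 512)
  expect_length(y, 512)
  expect_lt(max(abs(y - 1)), 1e-6)             # DC preserved
  t <- seq(0, 2, by = 1 / 2048)
  s <- sin(2 * pi * 10 * t)
  y2 <- downsample(s, 2048, 512)
  core <- y2[100:(length(y2) - 100)]
  expect_equal(max(abs(core)), 1, tolerance = 0.01)  # 10 Hz amplitude kept
  expect_error(downsample(x, 2048, 500), class = "unsupported_ratio")
})

test_that("planted bad channels are detected by the right criteria", {
  set.seed(21)
  fs <- 512
  t <- seq(0, 20, by = 1 / fs)
  # 63 clean sinusoid-mixture channels + structure
  mk <- function() 10 * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)) +
    5 * sin(2 * pi * 6 * t + runif(1, 0, 2 * pi)) + rnorm(length(t))
  x <- t(vapply(1:64, function(i) mk(), numeric(length(t))))
  # high-amplitude white-noise channel
  x[17, ] <- rnorm(length(t), 0, 80)
  bad <- detect_bad_channels(x)
  expect_true(17 %in% bad)
  expect_lte(length(bad), 3)
  # flat channel flagged via covariance
  x2 <- t(vapply(1:64, function(i) mk(), numeric(length(t))))
  x2[5, ] <- 0
  bad2 <- detect_bad_channels(x2)
  expect_true(5 %in% bad2)
  expect_true("covariance" %in% attr(bad2, "criteria")[[match(5, bad2)]])
  # identical channels: SD-0 guard flags nothing
  same <- matrix(rep(sin(2 * pi * 3 * t), 16), 16, byrow = TRUE)
  expect_length(detect_bad_channels(same), 0)
  expect_error(detect_bad_channels(matrix(rnorm(40), 4)), class = "invalid_config")
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  m <- test_montage
  x <- matrix(5, 64, 10)
  # constant field reproduced exactly
  y <- interpolate_spherical(x, bad = c(3, 40), m)
  expect_equal(y, x, tolerance = 1e-6)
  # smooth dipolar field, leave-one-out: < 5% RMS error
  p <- as.matrix(m[, c("x", "y", "z")])
  dip <- c(0.3, 0.5, 0.8)
  dip <- dip / sqrt(sum(dip^2))
  field <- (p %*% dip)[, 1]
  xf <- matrix(field, 64, 4)
  errs <- vapply(c(10, 25, 48), function(ch) {
    rec <- interpolate_spherical(xf, ch, m)
    abs(rec[ch, 1] - field[ch])
  }, 0)
  expect_lt(max(errs) / sqrt(mean(field^2)), 0.05)
  # zero bad channels: identity; all-bad: error
  expect_identical(interpolate_spherical(xf, integer(0), m), xf)
  expect_error(interpolate_spherical(xf, 1:62, m), class = "unrecoverable")
})

test_that("average reference zeroes the channel mean at every sample", {
  set.seed(22)
  x <- matrix(rnorm(64 * 100), 64)
  y <- rereference_average(x)
  expect_lt(max(abs(colMeans(y))), 1e-12)
  # re-referencing already-zero-mean data changes nothing
  expect_equal(rereference_average(y), y, tolerance = 1e-12)
  # constant offset on all channels maps to zero
  expect_lt(max(abs(rereference_average(matrix(7, 8, 5)))), 1e-12)
  expect_error(rereference_average(matrix(1, 1, 5)), class = "invalid_config")
})

test_that("epoching indexes correctly and baselines to zero", {
  fs <- 512
  n <- fs * 10
  tt <- (0:(n - 1)) / fs
  x <- rbind(sin(2 * pi * 3 * tt), cos(2 * pi * 5 * tt))
  m2 <- test_montage[1:2, ]
  ev <- c(1024, 2048, 4000)
  es <- suppressMessages(
    epoch_and_baseline(x, fs, ev, c(-200, 800), c(-100, 0), m2))
  expect_equal(dim(es$data), c(3, 2, 513))
  # epoch samples equal the analytic values minus the baseline mean
  off <- seq(round(-200 / (1000 / fs)), round(800 / (1000 / fs)))
  raw <- x[1, 1024 + off]
  bsel <- es$time_ms >= -100 & es$time_ms <= 0
  expect_equal(es$data[1, 1, ], raw - mean(raw[bsel]), tolerance = 1e-12)
  # baseline mean is zero for every epoch/channel
  bmeans <- apply(es$data[, , bsel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bmeans)), 1e-12)
  # constant channel maps to all zeros
  xc <- matrix(4, 1, n)
  esc <- epoch_and_baseline(xc, fs, ev, c(-200, 800), c(-100, 0),
                            test_montage[1, , drop = FALSE])
  expect_lt(max(abs(esc$data)), 1e-12)
  # events at the edges are skipped; none left = error
  expect_message(
    epoch_and_baseline(x, fs, c(10, 2048), c(-200, 800), c(-100, 0), m2),
    "skipped")
  expect_error(
    epoch_and_baseline(x, fs, c(10), c(-200, 800), c(-100, 0), m2),
    class = "empty_set")
})

test_that("epoch rejection fires the right rule per planted artifact", {
  set.seed(23)
  es <- gen_epoch_set(default_templates("correct_rejection"), 40,
                      noise = list(sd_uv = 8, exponent = 1, lambda = 0.5),
                      seed = 31)
  # clean set: no voltage rejections (all within +/-150 by construction)
  r0 <- reject_epochs(es)
  expect_false(any(r0$log$rule == "voltage"))
  # 200-uV sample: voltage rule
  es1 <- es
  es1$data[7, 12, 100] <- 200
  r1 <- reject_epochs(es1)
  expect_true(7 %in% r1$rejected)
  expect_true(any(r1$log$epoch == 7 & r1$log$rule == "voltage"))
  # 30-Hz burst raising 20-40 Hz band power ~30 dB: high-band rule
  es2 <- gen_epoch_set(default_templates("correct_rejection"), 40,
                       noise = list(sd_uv = 4, exponent = 1, lambda = 0.5),
                       seed = 32)
  burst <- 60 * sin(2 * pi * 30 * es2$time_ms / 1000)
  es2$data[5, 3, ] <- es2$data[5, 3, ] + burst
  r2 <- reject_epochs(es2)
  expect_true(5 %in% r2$rejected)
  expect_true(any(r2$log$epoch == 5 & r2$log$rule == "spectrum_high"))
  # rejection is idempotent on the kept set
  r3 <- reject_epochs(r2$kept)
  expect_lte(length(r3$rejected), 1)
  expect_error(reject_epochs(epoch_set(es$data[1:2, , , drop = FALSE],
                                       es$montage, es$sample_rate_hz,
                                       es$time_ms)),
               class = "invalid_config")
})

test_that("ERP averaging is the pointwise epoch mean", {
  es <- gen_epoch_set(default_templates("false_alarm"), 1,
                      noise = list(sd_uv = 0), lock = "response_onset")
  w1 <- average_erp(es)
  expect_equal(w1$data, es$data[1, , ])        # single epoch: itself
  expect_equal(w1$n_epochs, 1)
  es2 <- gen_epoch_set(default_templates("false_alarm"), 80,
                       noise = list(sd_uv = 6, exponent = 1, lambda = 0),
                       seed = 3, lock = "response_onset")
  w2 <- average_erp(es2)
  tmpl <- average_erp(gen_epoch_set(default_templates("false_alarm"), 1,
                                    noise = list(sd_uv = 0),
                                    lock = "response_onset"))$data
  # template + zero-mean noise: average approaches the template (CLT scale)
  expect_lt(max(abs(w2$data - tmpl)), 6 / sqrt(80) * 5)
})
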
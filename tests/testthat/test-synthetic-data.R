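test_that("trial sequences have the designed block composition", {
  s <- gen_trial_sequence(240, 0.13, 1017, seed = 1)
  expect_equal(sum(s$trial_type == "NoGo"), 31)
  expect_equal(sum(s$trial_type == "Go"), 209)
  expect_equal(unique(diff(s$onset_ms)), 1017)
  expect_equal(s$trial_type[1], "Go")          # block-initial trial is Go
  # forced counts at other configurations
  s2 <- gen_trial_sequence(10, 0.5, 1000, seed = 2)
  expect_equal(sum(s2$trial_type == "NoGo"), 5)
  expect_error(gen_trial_sequence(1, 0.13, 1017), class = "invalid_config")
  expect_error(gen_trial_sequence(10, 0, 1017), class = "invalid_config")
  expect_error(gen_trial_sequence(10, 1, 1017), class = "invalid_config")
  # determinism
  expect_identical(gen_trial_sequence(240, 0.13, seed = 7),
                   gen_trial_sequence(240, 0.13, seed = 7))
})

test_that("responses follow the configured hit and false-alarm rates", {
  s <- do.call(rbind, lapply(1:42, function(b)
    gen_trial_sequence(240, 0.5, 1000, seed = b, block_id = b)))
  pars <- list(hit_rate = 0.95, fa_rate = 0.4, rt_mean_ms = 390, rt_sd_ms = 47)
  r <- gen_responses(s, pars, seed = 1)
  go <- r$trial_type == "Go"
  n_go <- sum(go)
  n_nogo <- sum(!go)
  hr_emp <- mean(!is.na(r$response_ms[go]))
  fa_emp <- mean(!is.na(r$response_ms[!go]))
  expect_lt(abs(hr_emp - 0.95), 3 * sqrt(0.95 * 0.05 / n_go))
  expect_lt(abs(fa_emp - 0.4), 3 * sqrt(0.4 * 0.6 / n_nogo))
  # degenerate rates
  r2 <- gen_responses(s, list(hit_rate = 1, fa_rate = 0,
                              rt_mean_ms = 390, rt_sd_ms = 47), seed = 2)
  expect_true(all(!is.na(r2$response_ms[r2$trial_type == "Go"])))
  expect_true(all(is.na(r2$response_ms[r2$trial_type == "NoGo"])))
  # RT floor and determinism
  expect_true(all(r$response_ms >= 100, na.rm = TRUE))
  expect_identical(gen_responses(s, pars, seed = 5),
                   gen_responses(s, pars, seed = 5))
  expect_error(gen_responses(s, list(hit_rate = 0.9, fa_rate = 0.1,
                                     rt_mean_ms = -5, rt_sd_ms = 47)),
               class = "invalid_config")
})

test_that("gait traces segment into the expected strike count and jitter scales DTW", {
  tr <- gen_gait_trace(60, 1.1, 0, seed = 1)
  strikes <- detect_heel_strikes(tr$xyz[, 3])
  expect_equal(length(strikes), 54)            # ~ duration / period
  cycles <- lapply(segment_cycles(tr, strikes), resample_cycle)
  expect_equal(mean_dtw(cycles)$mean_dtw_m, 0) # jitter 0 => identical cycles
  # monotone in jitter over seeds
  md <- function(j, seed) {
    t2 <- gen_gait_trace(30, 1.1, j, seed = seed)
    st <- detect_heel_strikes(t2$xyz[, 3])
    mean_dtw(lapply(segment_cycles(t2, st), resample_cycle))$mean_dtw_m
  }
  wins <- sum(vapply(1:20, function(s) md(0.02, s) > md(0.005, s), TRUE))
  expect_gte(wins, 19)
  expect_error(gen_gait_trace(2, 1.1, 0), class = "too_short")
})

test_that("epoch sets reproduce templates, injected deltas and the CLT noise law", {
  tpl <- default_templates("correct_rejection")
  es0 <- gen_epoch_set(tpl, 4, noise = list(sd_uv = 0), seed = 1)
  w0 <- average_erp(es0)
  # zero noise: every epoch (hence the mean) equals the template field
  expect_equal(es0$data[1, , ], w0$data, tolerance = 1e-12)
  expect_equal(range(es0$time_ms), c(-200, 800))
  # injected walking-minus-sitting delta at FCz in the N2 window, zero noise
  eff <- list(list(electrodes = "FCz", window_ms = c(200, 350), delta_uv = -2))
  es1 <- gen_epoch_set(tpl, 4, effect_map = eff, noise = list(sd_uv = 0), seed = 1)
  d <- average_erp(es1)$data - w0$data
  fcz <- match("FCz", test_montage$label)
  sel <- es0$time_ms >= 200 & es0$time_ms <= 350
  expect_equal(unique(round(d[fcz, sel], 12)), -2)
  expect_true(all(abs(d[-fcz, ]) < 1e-12))
  expect_error(gen_epoch_set(tpl, 4, effect_map = list(list(
    electrodes = "XX9", window_ms = c(0, 100), delta_uv = 1))),
    class = "unknown_channel")
  # CLT: SEM of the mean within 20% of sd/sqrt(n)
  es2 <- gen_epoch_set(tpl, 60, noise = list(sd_uv = 10, exponent = 1,
                                             lambda = 0.5), seed = 2)
  sem <- apply(es2$data, c(2, 3), sd) / sqrt(60)
  expect_lt(abs(mean(sem) - 10 / sqrt(60)) / (10 / sqrt(60)), 0.2)
  # response-locked window
  es3 <- gen_epoch_set(default_templates("false_alarm"), 3,
                       noise = list(sd_uv = 0), lock = "response_onset")
  expect_equal(range(es3$time_ms), c(-500, 500))
})

test_that("template windows are constrained to their canonical component ranges", {
  expect_error(erp_template("N2", -3, window_ms = c(100, 350)),
               class = "invalid_config")
  expect_error(erp_template("nope", 1), class = "invalid_config")
  tp <- erp_template("P3", 5)
  expect_equal(tp$window_ms, c(350, 600))
})

test_that("a fixed seed reproduces the cohort byte-for-byte", {
  cfg <- list(cohort = list(n_imp = 1, n_nimp = 1),
              task = list(blocks_per_condition = 1, trials_per_block = 40),
              gait = list(duration_s = 6), eeg = list(n_epochs = 3))
  c1 <- simulate_cohort(cfg, seed = 42)
  c2 <- simulate_cohort(cfg, seed = 42)
  expect_identical(c1$participants, c2$participants)
  # trial-count conservation per block
  tr <- c1$participants[[1]]$trials
  counts <- table(tr$block_id)
  expect_true(all(counts == 40))
})
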
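# Synthetic Go/NoGo behavioral streams.
#
# The generated world mirrors the task design the pipeline assumes: blocks of
# 240 trials at a fixed 1,017-ms stimulus-onset asynchrony, 13% NoGo trials
# (a NoGo being a repeat of the immediately preceding image), responses drawn
# per-trial with configurable hit/false-alarm probabilities and a truncated
# normal response-time distribution.

#' Generate one block's Go/NoGo trial sequence
#'
#' NoGo trials are placed uniformly at random among positions 2..n (the first
#' trial of a block is always Go, since a NoGo is defined as a repeat of the
#' immediately preceding image). Onsets are at `(k - 1) * soa_ms`.
#'
#' @param n_trials number of trials in the block (>= 2)
#' @param nogo_fraction fraction of NoGo trials, strictly in (0, 1); the NoGo
#'   count is `round(n_trials * nogo_fraction)`
#' @param soa_ms stimulus-onset asynchrony in ms
#' @param seed optional RNG seed for reproducible placement
#' @param block_id,motor_condition bookkeeping labels carried on each trial
#' @return data.frame of trial records: `block_id`, `trial_idx`, `onset_ms`,
#'   `trial_type` ("Go"/"NoGo"), `response_ms` (NA, filled by
#'   [gen_responses()]), `motor_condition`
#' @export
#' @examples
#' seq1 <- gen_trial_sequence(240, 0.13, 1017, seed = 1)
#' table(seq1$trial_type)  # 209 Go, 31 NoGo
gen_trial_sequence <- function(n_trials, nogo_fraction, soa_ms = 1017,
                               seed = NULL, block_id = 1L,
                               motor_condition = "sitting") {
  if (n_trials < 2)
    stop_mobidt("invalid_config", "a block needs at least 2 trials")
  if (!is.finite(nogo_fraction) || nogo_fraction <= 0 || nogo_fraction >= 1)
    stop_mobidt("invalid_config", "nogo_fraction must be strictly inside (0, 1)")
  if (soa_ms <= 0)
    stop_mobidt("invalid_config", "soa_ms must be positive")
  n_nogo <- round(n_trials * nogo_fraction)
  if (n_nogo < 1 || n_nogo > n_trials - 1)
    stop_mobidt("invalid_config", "nogo_fraction leaves no room for Go trials")
  with_seed(seed, {
    pos <- sample(2:n_trials, n_nogo)
    type <- rep("Go", n_trials)
    type[pos] <- "NoGo"
    data.frame(block_id = as.integer(block_id),
               trial_idx = seq_len(n_trials),
               onset_ms = (seq_len(n_trials) - 1) * soa_ms,
               trial_type = type,
               response_ms = NA_real_,
               motor_condition = motor_condition,
               stringsAsFactors = FALSE)
  })
}

#' Draw a truncated-normal response latency
#' @noRd
rt_truncnorm <- function(n, mean_ms, sd_ms, floor_ms) {
  lo <- pnorm(floor_ms, mean_ms, sd_ms)
  qnorm(runif(n, lo, 1), mean_ms, sd_ms)
}

#' Simulate button-press responses for a trial sequence
#'
#' Go trials receive a response with probability `hit_rate`, NoGo trials with
#' probability `fa_rate`; latencies are truncated-normal (floor at
#' `rt_floor_ms`).
#'
#' @param trials data.frame from [gen_trial_sequence()]
#' @param params list with `hit_rate`, `fa_rate` (in `[0, 1]`), `rt_mean_ms`,
#'   `rt_sd_ms`, optional `rt_floor_ms` (default 100)
#' @param seed optional RNG seed
#' @return `trials` with `response_ms` filled in (NA = no response)
#' @export
gen_responses <- function(trials, params, seed = NULL) {
  hr <- params$hit_rate
  far <- params$fa_rate
  mu <- params$rt_mean_ms
  sdv <- params$rt_sd_ms
  floor_ms <- params$rt_floor_ms %||% 100
  if (any(!is.finite(c(hr, far))) || hr < 0 || hr > 1 || far < 0 || far > 1)
    stop_mobidt("invalid_config", "hit_rate and fa_rate must lie in [0, 1]")
  if (any(!is.finite(c(mu, sdv, floor_ms))) || mu <= 0 || sdv < 0 || floor_ms <= 0)
    stop_mobidt("invalid_config", "RT parameters must be positive")
  with_seed(seed, {
    n <- nrow(trials)
    go <- trials$trial_type == "Go"
    respond <- logical(n)
    respond[go] <- runif(sum(go)) < hr
    respond[!go] <- runif(sum(!go)) < far
    rt <- rep(NA_real_, n)
    if (any(respond))
      rt[respond] <- rt_truncnorm(sum(respond), mu, sdv, floor_ms)
    trials$response_ms <- rt
    trials
  })
}
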
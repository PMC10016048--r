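# Go/NoGo behavioral scoring: response-time gating, trial-outcome
# classification, signal-detection sensitivity (d') and mean Go RT.

#' Drop premature responses
#'
#' Responses at or before `min_rt_ms` post-stimulus-onset are treated as
#' delayed responses to the previous trial and removed (the trial becomes a
#' non-response trial); the boundary is exclusive, i.e. a response is kept
#' only when strictly later than `min_rt_ms`.
#'
#' @param trials trial data.frame (see [gen_trial_sequence()])
#' @param min_rt_ms acceptance gate in ms (default 183)
#' @return `trials` with premature `response_ms` set to NA
#' @export
filter_responses <- function(trials, min_rt_ms = 183) {
  if (min_rt_ms <= 0)
    stop_mobidt("invalid_config", "min_rt_ms must be positive")
  drop <- !is.na(trials$response_ms) & trials$response_ms <= min_rt_ms
  trials$response_ms[drop] <- NA_real_
  trials
}

#' Classify trial outcomes
#'
#' Adds `outcome` (hit / miss / correct_rejection / false_alarm) and
#' `preceded_by_hit` (TRUE iff the immediately preceding trial within the
#' same block is a hit; block-initial trials get FALSE). The
#' `preceded_by_hit` flag defines the EEG-eligible subset of correct
#' rejections and false alarms.
#'
#' @param trials trial data.frame, ordered by `trial_idx` within block
#' @return `trials` with `outcome` and `preceded_by_hit` columns
#' @export
classify_trials <- function(trials) {
  ord_ok <- tapply(trials$trial_idx, trials$block_id,
                   function(v) all(diff(v) > 0))
  if (!all(unlist(ord_ok)))
    stop_mobidt("ordering", "trial_idx must be strictly increasing within block")
  responded <- !is.na(trials$response_ms)
  go <- trials$trial_type == "Go"
  outcome <- ifelse(go,
                    ifelse(responded, "hit", "miss"),
                    ifelse(responded, "false_alarm", "correct_rejection"))
  prev_hit <- logical(nrow(trials))
  same_block <- c(FALSE, trials$block_id[-1] == trials$block_id[-nrow(trials)])
  prev_hit[-1] <- outcome[-nrow(trials)] == "hit"
  trials$outcome <- outcome
  trials$preceded_by_hit <- prev_hit & same_block
  trials
}

#' Signal-detection sensitivity index d'
#'
#' `d' = qnorm(HR) - qnorm(FAR)` with a log-linear edge correction (add 0.5
#' successes and 1 trial) applied whenever a rate is 0 or 1, so the score
#' stays finite. Antisymmetric under swapping HR and FAR.
#'
#' @param hit_rate,fa_rate raw proportions in `[0, 1]`
#' @param n_go,n_nogo trial counts underlying the rates (> 0)
#' @return d' (standardized score)
#' @export
#' @examples
#' compute_dprime(0.8413, 0.1587, 209, 31)  # ~ 2.0
compute_dprime <- function(hit_rate, fa_rate, n_go, n_nogo) {
  if (n_go <= 0 || n_nogo <= 0)
    stop_mobidt("undefined_rate", "trial counts must be positive")
  adj <- function(rate, n) {
    if (rate <= 0 || rate >= 1) (rate * n + 0.5) / (n + 1) else rate
  }
  qnorm(adj(hit_rate, n_go)) - qnorm(adj(fa_rate, n_nogo))
}

#' Mean response time over hits
#'
#' @param trials classified trials (after [filter_responses()] and
#'   [classify_trials()])
#' @return arithmetic mean hit latency in ms
#' @export
mean_go_rt <- function(trials) {
  rt <- trials$response_ms[trials$outcome == "hit"]
  rt <- rt[!is.na(rt)]
  if (length(rt) == 0)
    stop_mobidt("empty_sample", "no hits to average")
  mean(rt)
}

#' Per-participant, per-condition behavioral summary
#'
#' Applies the RT gate, classifies outcomes, pools counts across all blocks
#' of each motor condition and reports hit/false-alarm rates, d' and mean Go
#' RT.
#'
#' @param trials trial data.frame for one participant (all blocks, both
#'   motor conditions)
#' @param participant_id identifier carried on the output
#' @param min_rt_ms RT acceptance gate (default 183 ms)
#' @return data.frame, one row per motor condition: counts (`n_hits`,
#'   `n_misses`, `n_cr`, `n_fa`), `hit_rate`, `fa_rate`, `dprime`,
#'   `mean_go_rt_ms`
#' @export
behavioral_summary <- function(trials, participant_id = NA, min_rt_ms = 183) {
  trials <- classify_trials(filter_responses(trials, min_rt_ms))
  out <- lapply(split(trials, trials$motor_condition), function(tr) {
    n_hits <- sum(tr$outcome == "hit")
    n_misses <- sum(tr$outcome == "miss")
    n_cr <- sum(tr$outcome == "correct_rejection")
    n_fa <- sum(tr$outcome == "false_alarm")
    hr <- n_hits / (n_hits + n_misses)
    far <- n_fa / (n_fa + n_cr)
    data.frame(participant_id = participant_id,
               motor_condition = tr$motor_condition[1],
               n_hits = n_hits, n_misses = n_misses,
               n_cr = n_cr, n_fa = n_fa,
               hit_rate = hr, fa_rate = far,
               dprime = compute_dprime(hr, far, n_hits + n_misses, n_fa + n_cr),
               mean_go_rt_ms = mean_go_rt(tr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
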
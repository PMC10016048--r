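# Synthetic ERP epoch sets.
#
# Epochs are channels x time voltage arrays built as a sum of component
# templates (Gaussian time course x Gaussian scalp weighting around a peak
# electrode), optional injected condition effects (amplitude deltas over an
# electrode set and latency window), and spatially correlated 1/f noise.
# Epochs are generated directly at the target sampling rate; no continuous
# raw recording is simulated.

.component_windows <- list(
  N2  = c(200, 350),
  P3  = c(350, 600),
  ERN = c(-50, 100),
  PMP = c(-210, -50)
)

#' ERP component template
#'
#' @param name one of "N2", "P3", "ERN", "PMP"
#' @param amplitude_uv signed peak amplitude in microvolts (sign = polarity)
#' @param peak_latency_ms peak latency; defaults to the window midpoint
#' @param window_ms latency window; defaults to the canonical window for the
#'   component (N2 200-350, P3 350-600, ERN -50-100, PMP -210--50 ms)
#' @param center_channel electrode at the scalp maximum
#' @param scalp_sigma spatial Gaussian width (chord distance on unit sphere)
#' @return list of class `erp_template`
#' @export
erp_template <- function(name, amplitude_uv,
                         peak_latency_ms = NULL, window_ms = NULL,
                         center_channel = "FCz", scalp_sigma = 0.6) {
  if (!name %in% names(.component_windows))
    stop_mobidt("invalid_config", "unknown ERP component name")
  canonical <- .component_windows[[name]]
  window_ms <- window_ms %||% canonical
  if (window_ms[1] < canonical[1] - 1e-9 || window_ms[2] > canonical[2] + 1e-9)
    stop_mobidt("invalid_config",
                sprintf("%s window must lie within [%g, %g] ms", name,
                        canonical[1], canonical[2]))
  peak_latency_ms <- peak_latency_ms %||% mean(window_ms)
  structure(list(name = name, amplitude_uv = amplitude_uv,
                 peak_latency_ms = peak_latency_ms, window_ms = window_ms,
                 center_channel = center_channel, scalp_sigma = scalp_sigma),
            class = "erp_template")
}

#' Default template sets per cognitive condition
#'
#' Stimulus-locked correct rejections carry an N2 (frontocentral negativity)
#' and a P3 (centroparietal positivity); response-locked false alarms carry a
#' premovement positivity and an error-related negativity, both frontocentral.
#'
#' @param condition "correct_rejection" or "false_alarm"
#' @return list of [erp_template()] objects
#' @export
default_templates <- function(condition = c("correct_rejection", "false_alarm")) {
  condition <- match.arg(condition)
  if (condition == "correct_rejection") {
    list(erp_template("N2", -3, peak_latency_ms = 275, center_channel = "FCz"),
         erp_template("P3", 6, peak_latency_ms = 450, center_channel = "Pz",
                      scalp_sigma = 0.9))
  } else {
    list(erp_template("PMP", 3, peak_latency_ms = -130, center_channel = "Cz"),
         erp_template("ERN", -4, peak_latency_ms = 40, center_channel = "FCz"))
  }
}

#' Scalp weight vector for a template over a montage
#' @noRd
scalp_weights <- function(template, montage) {
  idx <- match(template$center_channel, montage$label)
  if (is.na(idx))
    stop_mobidt("unknown_channel",
                sprintf("electrode %s not in montage", template$center_channel))
  p <- as.matrix(montage[, c("x", "y", "z")])
  d <- sqrt(rowSums((p - matrix(p[idx, ], nrow(p), 3, byrow = TRUE))^2))
  exp(-(d / template$scalp_sigma)^2 / 2)
}

#' Noiseless channels x time field for a template set (+ optional effects)
#' @noRd
template_field <- function(templates, effect_map, montage, time_ms) {
  nc <- nrow(montage)
  field <- matrix(0, nc, length(time_ms))
  for (tp in templates) {
    sigma_t <- diff(tp$window_ms) / 6
    course <- tp$amplitude_uv * exp(-((time_ms - tp$peak_latency_ms) / sigma_t)^2 / 2)
    field <- field + outer(scalp_weights(tp, montage), course)
  }
  for (ef in effect_map %||% list()) {
    idx <- match(ef$electrodes, montage$label)
    if (anyNA(idx))
      stop_mobidt("unknown_channel",
                  paste("effect electrodes not in montage:",
                        paste(ef$electrodes[is.na(idx)], collapse = ", ")))
    sel <- time_ms >= ef$window_ms[1] & time_ms <= ef$window_ms[2]
    field[idx, sel] <- field[idx, sel] + ef$delta_uv
  }
  field
}

#' Spatially correlated 1/f noise for a block of epochs
#'
#' Temporal spectrum ~ 1/f^exponent (plus a white floor), mixed across
#' channels with weights exp(-d/lambda) and rescaled so each sample's marginal
#' SD equals `sd_uv`.
#' @noRd
gen_noise_block <- function(n_epochs, n_chan, n_time, sd_uv, exponent,
                            lambda, dist = NULL) {
  if (sd_uv == 0) return(array(0, c(n_epochs, n_chan, n_time)))
  # temporal shaping via FFT of white noise (Hermitian-symmetric gain so the
  # inverse transform is real); f = 0 treated as f = 1 to avoid a DC blowup
  k <- 0:(n_time - 1)
  f_eff <- pmin(k, n_time - k)
  f_eff[f_eff == 0] <- 1
  shape <- f_eff^(-exponent / 2)
  W <- matrix(rnorm(n_time * n_epochs * n_chan), n_time)
  X <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE)) / n_time
  X <- X / sd(as.numeric(X))
  arr <- array(X, c(n_time, n_chan, n_epochs))
  # spatial mixing with exp(-d/lambda) rows, L2-normalized so the marginal
  # per-sample variance is preserved
  if (!is.null(dist) && lambda > 0) {
    M <- exp(-dist / lambda)
    M <- M / sqrt(rowSums(M^2))
    flat <- matrix(aperm(arr, c(1, 3, 2)), n_time * n_epochs, n_chan)
    arr <- aperm(array(flat %*% t(M), c(n_time, n_epochs, n_chan)), c(1, 3, 2))
  }
  aperm(arr, c(3, 2, 1)) * sd_uv
}

#' Generate a synthetic ERP epoch set
#'
#' @param templates list of [erp_template()] (e.g. [default_templates()])
#' @param n_epochs number of epochs
#' @param effect_map optional list of effects, each a list with `electrodes`
#'   (labels), `window_ms = c(lo, hi)` and `delta_uv` (amplitude change added
#'   to every epoch; used to inject walking-minus-sitting differences)
#' @param noise list with `sd_uv` (marginal noise SD per sample, microvolts),
#'   `exponent` (1/f temporal exponent, default 1) and `lambda` (spatial
#'   correlation length as chord distance, default 0.5; 0 = uncorrelated)
#' @param seed optional RNG seed
#' @param lock "stimulus_onset" (window -200..800 ms) or "response_onset"
#'   (window -500..500 ms)
#' @param condition condition label carried on the object
#' @param sample_rate_hz sampling rate of the generated epochs (default 512)
#' @param montage electrode montage (default [montage_biosemi64()])
#' @return `epoch_set` object; see [epoch_set()]
#' @export
gen_epoch_set <- function(templates, n_epochs, effect_map = NULL,
                          noise = list(sd_uv = 10, exponent = 1, lambda = 0.5),
                          seed = NULL,
                          lock = c("stimulus_onset", "response_onset"),
                          condition = "correct_rejection",
                          sample_rate_hz = 512,
                          montage = montage_biosemi64()) {
  lock <- match.arg(lock)
  window_ms <- if (lock == "stimulus_onset") c(-200, 800) else c(-500, 500)
  dt <- 1000 / sample_rate_hz
  time_ms <- seq(window_ms[1], window_ms[2], by = dt)
  nc <- nrow(montage)
  field <- template_field(templates, effect_map, montage, time_ms)
  with_seed(seed, {
    sd_uv <- noise$sd_uv %||% 10
    expo <- noise$exponent %||% 1
    lambda <- noise$lambda %||% 0.5
    dist <- if (lambda > 0) montage_distances(montage) else NULL
    arr <- gen_noise_block(n_epochs, nc, length(time_ms), sd_uv, expo,
                           lambda, dist = dist)
    for (e in seq_len(n_epochs))
      arr[e, , ] <- arr[e, , ] + field
    epoch_set(arr, montage = montage, sample_rate_hz = sample_rate_hz,
              time_ms = time_ms, lock = lock, condition = condition)
  })
}
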
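# Synthetic 3D heel-marker traces for treadmill walking.
#
# Each gait cycle is an instance of a smooth template heel path (fore-aft
# near-sinusoidal excursion in the treadmill frame, vertical double-bump with
# a swing-phase lift, small lateral sway) perturbed per cycle by a smooth
# low-order harmonic field whose amplitude is the `jitter_m` knob. Stride
# periods are quantized to the 360-per-second sample grid so that at
# jitter 0 every segmented, resampled cycle is sample-identical (mean DTW
# exactly 0), which anchors the variability scale of the whole gait module.

#' Template heel path over one gait cycle
#' @param phase vector in [0, 1)
#' @return matrix phase-points x 3 (X lateral, Y vertical, Z fore-aft), meters
#' @noRd
gait_template <- function(phase) {
  z <- 0.35 * cos(2 * pi * phase)                       # fore-aft, strike at 0
  y <- 0.03 * (1 - cos(4 * pi * phase)) / 2 +
    0.10 * exp(-((phase - 0.72) / 0.08)^2)              # stance bumps + swing lift
  x <- 0.02 * sin(2 * pi * phase)                       # lateral sway
  cbind(x, y, z)
}

#' Smooth zero-mean harmonic perturbation over one cycle, unit scale
#' @noRd
gait_perturbation <- function(phase, n_harm = 3) {
  out <- matrix(0, length(phase), 3)
  for (axis in 1:3) {
    w <- 0
    for (h in seq_len(n_harm)) {
      ab <- rnorm(2) / sqrt(h)
      w <- w + ab[1] * sin(2 * pi * h * phase) + ab[2] * cos(2 * pi * h * phase)
    }
    out[, axis] <- w
  }
  # normalize so the pooled per-sample SD is ~1 before scaling by jitter_m
  out / sqrt(sum(1 / seq_len(n_harm)))
}

#' Generate a synthetic heel-marker trace for one foot
#'
#' @param duration_s trace duration in seconds (must cover >= 3 stride periods)
#' @param stride_period_s nominal stride period in seconds
#' @param jitter_m per-stride shape perturbation scale in meters (0 gives
#'   perfectly repeating cycles)
#' @param seed optional RNG seed
#' @param sample_rate_hz motion-capture sampling rate (default 360)
#' @param foot label, "left" or "right"
#' @return list of class `gait_trace`: `foot`, `sample_rate_hz`, `t` (s) and
#'   `xyz` (samples x 3 matrix, meters; columns X lateral, Y vertical, Z
#'   fore-aft)
#' @export
#' @examples
#' tr <- gen_gait_trace(30, 1.1, 0.01, seed = 1)
#' length(detect_heel_strikes(tr$xyz[, 3]))
gen_gait_trace <- function(duration_s, stride_period_s, jitter_m,
                           seed = NULL, sample_rate_hz = 360,
                           foot = "left") {
  if (stride_period_s <= 0)
    stop_mobidt("invalid_config", "stride_period_s must be positive")
  if (jitter_m < 0)
    stop_mobidt("invalid_config", "jitter_m must be non-negative")
  if (duration_s < 3 * stride_period_s)
    stop_mobidt("too_short", "trace must cover at least 3 stride periods")
  with_seed(seed, {
    n_total <- floor(duration_s * sample_rate_hz)
    base_len <- round(stride_period_s * sample_rate_hz)  # sample-grid quantized
    pieces <- list()
    filled <- 0
    while (filled < n_total) {
      # stride-period jitter: smooth multiplicative, same scale as shape jitter
      len <- if (jitter_m > 0) {
        max(3L, base_len + as.integer(round(rnorm(1, 0, jitter_m / 0.35 *
                                                    0.5 * base_len))))
      } else base_len
      phase <- (seq_len(len) - 1) / len
      cyc <- gait_template(phase)
      if (jitter_m > 0)
        cyc <- cyc + jitter_m * gait_perturbation(phase)
      pieces[[length(pieces) + 1L]] <- cyc
      filled <- filled + len
    }
    xyz <- do.call(rbind, pieces)[seq_len(n_total), , drop = FALSE]
    colnames(xyz) <- c("X", "Y", "Z")
    structure(list(foot = foot, sample_rate_hz = sample_rate_hz,
                   t = (seq_len(n_total) - 1) / sample_rate_hz, xyz = xyz),
              class = "gait_trace")
  })
}
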
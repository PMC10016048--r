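# ERP preprocessing: containers, bad-channel handling, re-referencing,
# epoching, baseline correction, artifact-based epoch rejection, averaging.
# All voltages are in microvolts and all times in ms relative to the lock
# event; channel order is fixed by the montage.

#' ERP epoch container
#'
#' @param data numeric array, epochs x channels x time, microvolts
#' @param montage electrode montage data.frame (`label`, `x`, `y`, `z`)
#' @param sample_rate_hz sampling rate
#' @param time_ms time vector in ms relative to the lock event
#' @param lock "stimulus_onset" or "response_onset"
#' @param condition free-form condition label (e.g. "correct_rejection.walking")
#' @return list of class `epoch_set`
#' @export
epoch_set <- function(data, montage, sample_rate_hz, time_ms,
                      lock = "stimulus_onset", condition = "") {
  if (length(dim(data)) != 3)
    stop_mobidt("invalid_config", "data must be epochs x channels x time")
  if (dim(data)[2] != nrow(montage))
    stop_mobidt("invalid_config", "channel dimension must match the montage")
  if (dim(data)[3] != length(time_ms))
    stop_mobidt("invalid_config", "time dimension must match the time vector")
  structure(list(data = data, montage = montage,
                 sample_rate_hz = sample_rate_hz, time_ms = time_ms,
                 lock = lock, condition = condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g Hz), %s, %s\n",
              d[1], d[2], d[3], x$sample_rate_hz, x$lock, x$condition))
  invisible(x)
}

#' Z-scores across a vector with a zero-SD guard
#' @noRd
guarded_z <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Negative mean log-probability of values under a pooled empirical density
#' @noRd
neg_log_prob <- function(values, ref, nbins = 100) {
  rng <- range(ref)
  if (diff(rng) == 0) return(rep(0, nrow(values)))
  br <- seq(rng[1] - 1e-12, rng[2] + 1e-12, length.out = nbins + 1)
  dens <- tabulate(findInterval(ref, br, all.inside = TRUE), nbins) / length(ref)
  dens <- pmax(dens, 1 / (10 * length(ref)))
  idx <- findInterval(values, br, all.inside = TRUE)
  p <- matrix(dens[idx], nrow(values))
  -rowMeans(log(p))
}

#' Detect bad channels in continuous data
#'
#' A channel is flagged if any of four across-channel statistics is extreme:
#' sample kurtosis (|z| > `k_sd`), joint negative log-probability of its
#' values under the pooled all-channel empirical distribution (|z| > `k_sd`),
#' band-averaged log-spectral deviation from the across-channel mean spectrum
#' (|z| > `k_sd`), or mean absolute covariance with the other channels
#' (|z| > `cov_sd`). Zero across-channel SDs flag nothing for that criterion.
#'
#' @param x channels x time matrix of continuous data
#' @param k_sd threshold (SD units) for kurtosis/probability/spectrum
#' @param cov_sd threshold (SD units) for the covariance criterion
#' @return integer vector of flagged channel indices (possibly empty), with a
#'   `criteria` attribute naming the rule(s) that fired per channel
#' @export
detect_bad_channels <- function(x, k_sd = 5, cov_sd = 3) {
  nc <- nrow(x)
  if (nc < 8)
    stop_mobidt("invalid_config", "need at least 8 channels for stable statistics")
  kurt <- apply(x, 1, kurtosis_moment)
  kurt[!is.finite(kurt)] <- 0
  prob <- neg_log_prob(x, as.numeric(x))
  # log spectrum averaged over frequencies, deviation from channel mean
  nfft <- 2^floor(log2(min(ncol(x), 4096)))
  seg <- x[, seq_len(nfft), drop = FALSE]
  sp <- abs(stats::mvfft(t(seg)))^2
  sp <- sp[2:(nfft / 2), , drop = FALSE]
  logsp <- log10(pmax(sp, .Machine$double.xmin))
  dev_sp <- colMeans(abs(logsp - rowMeans(logsp)))
  cv <- stats::cov(t(x))
  mac <- (rowSums(abs(cv)) - abs(diag(cv))) / (nc - 1)
  flags <- list(kurtosis = abs(guarded_z(kurt)) > k_sd,
                probability = abs(guarded_z(prob)) > k_sd,
                spectrum = abs(guarded_z(dev_sp)) > k_sd,
                covariance = abs(guarded_z(mac)) > cov_sd)
  bad <- which(Reduce(`|`, flags))
  attr(bad, "criteria") <- lapply(bad, function(i)
    names(flags)[vapply(flags, `[[`, TRUE, i)])
  bad
}

#' Legendre polynomial values P_0..P_L at x (recurrence)
#' @noRd
legendre_upto <- function(L, x) {
  out <- matrix(0, length(x), L + 1)
  out[, 1] <- 1
  if (L >= 1) out[, 2] <- x
  if (L >= 2) for (l in 2:L)
    out[, l + 1] <- ((2 * l - 1) * x * out[, l] - (l - 1) * out[, l - 1]) / l
  out
}

#' Perrin spherical-spline kernel g(cos(angle)) with order m
#' @noRd
spline_g <- function(cosang, m = 4, L = 20) {
  P <- legendre_upto(L, pmax(-1, pmin(1, cosang)))
  l <- seq_len(L)
  coef <- (2 * l + 1) / (l * (l + 1))^m
  matrix(P[, -1, drop = FALSE] %*% coef / (4 * pi),
         nrow = if (is.matrix(cosang)) nrow(cosang) else length(cosang))
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the flagged channels with order-4 spherical-spline estimates
#' computed from the good channels (Perrin-style, ridge-regularized); good
#' channels are untouched.
#'
#' @param x channels x time matrix
#' @param bad integer indices of channels to reconstruct (empty = identity)
#' @param montage electrode montage (positions projected to the unit sphere)
#' @param lambda ridge regularization added to the spline system diagonal
#' @return matrix with bad channels replaced
#' @export
interpolate_spherical <- function(x, bad, montage, lambda = 1e-5) {
  if (length(bad) == 0) return(x)
  nc <- nrow(x)
  good <- setdiff(seq_len(nc), bad)
  if (length(good) < 4)
    stop_mobidt("unrecoverable", "fewer than 4 good channels left")
  p <- as.matrix(montage[, c("x", "y", "z")])
  p <- p / sqrt(rowSums(p^2))
  cos_gg <- tcrossprod(p[good, , drop = FALSE])
  cos_bg <- tcrossprod(p[bad, , drop = FALSE], p[good, , drop = FALSE])
  G <- spline_g(cos_gg)
  Gb <- spline_g(cos_bg)
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(x[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  x[bad, ] <- Gb %*% w + matrix(c0, length(bad), ncol(x), byrow = TRUE)
  x
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample, so the channel mean is
#' zero at every timepoint afterwards.
#'
#' @param x channels x time matrix (>= 2 channels)
#' @return re-referenced matrix
#' @export
rereference_average <- function(x) {
  if (nrow(x) < 2)
    stop_mobidt("invalid_config", "average reference needs at least 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Cut epochs around events and baseline-correct
#'
#' @param x channels x time continuous matrix
#' @param sample_rate_hz sampling rate of `x`
#' @param event_samples 1-based sample indices of the lock events
#' @param window_ms epoch window, e.g. c(-200, 800)
#' @param baseline_ms baseline window, e.g. c(-100, 0); its per-channel mean
#'   is subtracted from each epoch
#' @param montage montage for the resulting [epoch_set()]
#' @param lock,condition labels carried on the result
#' @return `epoch_set`; events too close to the recording edges are skipped
#'   (count reported via message)
#' @export
epoch_and_baseline <- function(x, sample_rate_hz, event_samples,
                               window_ms, baseline_ms,
                               montage, lock = "stimulus_onset",
                               condition = "") {
  dt <- 1000 / sample_rate_hz
  off <- seq(round(window_ms[1] / dt), round(window_ms[2] / dt))
  time_ms <- off * dt
  keep <- event_samples + min(off) >= 1 & event_samples + max(off) <= ncol(x)
  if (sum(!keep) > 0)
    message(sum(!keep), " event(s) too close to the recording edges; skipped")
  ev <- event_samples[keep]
  if (length(ev) == 0)
    stop_mobidt("empty_set", "no events with a full epoch window")
  arr <- array(0, c(length(ev), nrow(x), length(off)))
  bsel <- time_ms >= baseline_ms[1] & time_ms <= baseline_ms[2]
  for (i in seq_along(ev)) {
    ep <- x[, ev[i] + off, drop = FALSE]
    arr[i, , ] <- ep - rowMeans(ep[, bsel, drop = FALSE])
  }
  epoch_set(arr, montage, sample_rate_hz, time_ms, lock, condition)
}

#' Per-epoch, per-channel band log-power (dB)
#' @noRd
epoch_band_db <- function(data, sample_rate_hz, band_hz) {
  d <- dim(data)
  n_time <- d[3]
  freqs <- (0:(n_time - 1)) * sample_rate_hz / n_time
  sel <- freqs >= band_hz[1] & freqs <= band_hz[2] & freqs <= sample_rate_hz / 2
  if (!any(sel)) sel[which.min(abs(freqs - mean(band_hz)))] <- TRUE
  flat <- matrix(aperm(data, c(3, 1, 2)), n_time)   # time x (epoch*chan)
  pw <- abs(stats::mvfft(flat))^2
  bp <- colMeans(pw[sel, , drop = FALSE])
  matrix(10 * log10(pmax(bp, .Machine$double.xmin)), d[1], d[2])
}

#' Artifact-based epoch rejection
#'
#' An epoch is removed when any criterion fires, with statistics computed once
#' on the incoming set (fixed order: voltage, kurtosis, probability, low-band
#' spectrum, high-band spectrum):
#' * absolute voltage beyond `max_uv` (default +/-150 microvolts) at any sample;
#' * per-channel sample kurtosis or joint negative log-probability more than
#'   `k_sd` (default 5) SDs from the across-epoch mean for that channel;
#' * 0-2 Hz band log-power deviating more than +/-`low_db` (default 50 dB)
#'   from the across-epoch mean (eye movements);
#' * 20-40 Hz band log-power deviating more than +`high_up_db` (25 dB) or
#'   -`high_down_db` (100 dB) from the across-epoch mean (muscle activity).
#'
#' @param epochs an [epoch_set()]
#' @param max_uv absolute-voltage threshold in microvolts
#' @param k_sd SD threshold for the kurtosis and probability criteria
#' @param low_db,high_up_db,high_down_db spectral thresholds in dB
#' @return list with `kept` (epoch_set), `log` (data.frame epoch x rule) and
#'   `rejected` (indices)
#' @export
reject_epochs <- function(epochs, max_uv = 150, k_sd = 5,
                          low_db = 50, high_up_db = 25, high_down_db = 100) {
  data <- epochs$data
  d <- dim(data)
  if (d[1] < 3)
    stop_mobidt("invalid_config", "need at least 3 epochs for rejection statistics")
  fs <- epochs$sample_rate_hz
  rules <- list()
  # 1. absolute voltage
  vmax <- apply(abs(data), 1, max)
  rules$voltage <- vmax > max_uv
  # 2. kurtosis per channel, z across epochs (vectorized over epoch*channel)
  flat <- matrix(data, d[1] * d[2], d[3])
  flat <- flat - rowMeans(flat)
  m2 <- rowMeans(flat^2)
  kurt <- matrix(rowMeans(flat^4) / m2^2, d[1], d[2])
  kurt[!is.finite(kurt)] <- 0
  kz <- apply(kurt, 2, guarded_z)
  rules$kurtosis <- apply(abs(kz) > k_sd, 1, any)
  # 3. joint probability per channel (density across that channel's values)
  pr <- matrix(0, d[1], d[2])
  for (ch in seq_len(d[2])) {
    vals <- matrix(data[, ch, ], d[1])
    pr[, ch] <- neg_log_prob(vals, as.numeric(vals))
  }
  pz <- apply(pr, 2, guarded_z)
  rules$probability <- apply(abs(pz) > k_sd, 1, any)
  # 4./5. spectral deviation from the across-epoch mean, per channel
  low <- epoch_band_db(data, fs, c(0, 2))
  low_dev <- sweep(low, 2, colMeans(low))
  rules$spectrum_low <- apply(abs(low_dev) > low_db, 1, any)
  high <- epoch_band_db(data, fs, c(20, 40))
  high_dev <- sweep(high, 2, colMeans(high))
  rules$spectrum_high <- apply(high_dev > high_up_db | high_dev < -high_down_db,
                               1, any)
  fired <- do.call(cbind, rules)
  rejected <- which(apply(fired, 1, any))
  if (length(rejected) == d[1])
    stop_mobidt("degenerate_set", "all epochs rejected")
  log <- data.frame(epoch = rep(seq_len(d[1]), ncol(fired)),
                    rule = rep(colnames(fired), each = d[1]),
                    fired = as.vector(fired))
  log <- log[log$fired, c("epoch", "rule")]
  rownames(log) <- NULL
  kept <- epochs
  kept$data <- data[setdiff(seq_len(d[1]), rejected), , , drop = FALSE]
  list(kept = kept, log = log, rejected = rejected)
}

#' Average epochs into an ERP waveform
#'
#' @param epochs an [epoch_set()] with at least one epoch
#' @return list of class `erp_waveform`: `data` (channels x time mean,
#'   microvolts), `n_epochs`, plus montage/time/lock/condition metadata
#' @export
average_erp <- function(epochs) {
  d <- dim(epochs$data)
  if (d[1] < 1) stop_mobidt("empty_sample", "no epochs to average")
  m <- colMeans(epochs$data, dims = 1)
  structure(list(data = m, n_epochs = d[1], montage = epochs$montage,
                 sample_rate_hz = epochs$sample_rate_hz,
                 time_ms = epochs$time_ms, lock = epochs$lock,
                 condition = epochs$condition),
            class = "erp_waveform")
}
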
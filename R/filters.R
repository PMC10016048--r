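# Chebyshev Type II filter design and zero-phase application.
#
# No signal-processing package ships with the supported stack, so the design
# chain (analog prototype -> lowpass transform -> bilinear transform ->
# second-order sections) is implemented here. It mirrors the classical
# textbook construction; the forward-backward pass uses steady-state initial
# conditions per section plus odd-reflection edge padding, so the net phase is
# zero and edge transients are suppressed.

#' Minimum Chebyshev Type II order for a lowpass specification
#' @noRd
cheb2_order <- function(wp, ws, apass_db, astop_db) {
  # wp, ws: normalized edges in (0,1), 1 = Nyquist; prewarped for bilinear
  WP <- tan(pi * wp / 2)
  WS <- tan(pi * ws / 2)
  gp <- 10^(0.1 * apass_db) - 1
  gs <- 10^(0.1 * astop_db) - 1
  ceiling(acosh(sqrt(gs / gp)) / acosh(WS / WP))
}

#' Analog Chebyshev Type II prototype (zeros, poles, gain), cutoff at the
#' stopband edge (normalized to 1 rad/s)
#' @noRd
cheb2_prototype <- function(n, astop_db) {
  de <- 1 / sqrt(10^(0.1 * astop_db) - 1)
  mu <- asinh(1 / de) / n
  m <- if (n %% 2) c(seq(-n + 1, -2, by = 2), seq(2, n - 1, by = 2))
       else seq(-n + 1, n - 1, by = 2)
  z <- -Conj(1i / sin(m * pi / (2 * n)))
  p0 <- -exp(1i * pi * seq(-n + 1, n - 1, by = 2) / (2 * n))
  p0 <- complex(real = sinh(mu) * Re(p0), imaginary = cosh(mu) * Im(p0))
  p <- 1 / p0
  k <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, k = k)
}

#' Digital Chebyshev II lowpass as second-order sections
#'
#' @param n filter order
#' @param w_stop normalized stopband edge (1 = Nyquist)
#' @param astop_db stopband attenuation in dB
#' @return list with `sos` (nsec x 6 matrix, gain folded into first section)
#' @noRd
cheb2_lowpass_sos <- function(n, w_stop, astop_db) {
  proto <- cheb2_prototype(n, astop_db)
  # lowpass-to-lowpass at the prewarped analog cutoff, then bilinear (fs = 2)
  fs <- 2
  warped <- 2 * fs * tan(pi * w_stop / fs)
  z <- proto$z * warped
  p <- proto$p * warped
  k <- proto$k * warped^(length(p) - length(z))
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  # pad zeros at z = -1 up to the pole count
  if (length(zd) < length(pd))
    zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  zpk_to_sos(zd, pd, kd)
}

#' Convert conjugate-paired digital zeros/poles/gain to second-order sections
#' @noRd
zpk_to_sos <- function(z, p, k) {
  pair_reps <- function(v) {
    # representatives: one of each conjugate pair (positive imag), plus reals
    im <- Im(v)
    reps <- v[im > 1e-9]
    reals <- Re(v[abs(im) <= 1e-9])
    list(cplx = reps, real = reals)
  }
  zz <- pair_reps(z)
  pp <- pair_reps(p)
  sections <- list()
  # order complex pole pairs by closeness to the unit circle (worst first is
  # irrelevant in double precision; keep deterministic ordering)
  if (length(pp$cplx)) {
    ord <- order(-abs(pp$cplx))
    pp$cplx <- pp$cplx[ord]
  }
  zc <- zz$cplx
  for (pk in pp$cplx) {
    if (length(zc)) {
      j <- which.min(abs(zc - pk))
      zk <- zc[j]
      zc <- zc[-j]
      b <- c(1, -2 * Re(zk), abs(zk)^2)
    } else b <- c(1, 0, 0)
    a <- c(1, -2 * Re(pk), abs(pk)^2)
    sections[[length(sections) + 1L]] <- c(b, a)
  }
  # leftover real poles/zeros (at most one of each for these designs)
  pr <- pp$real
  zr <- c(zz$real, rep(0, max(0, length(pr) - length(zz$real))))
  if (length(pr)) {
    for (i in seq_along(pr)) {
      b <- c(1, if (i <= length(zz$real)) -zz$real[i] else 0, 0)
      a <- c(1, -pr[i], 0)
      sections[[length(sections) + 1L]] <- c(b, a)
    }
  }
  sos <- do.call(rbind, sections)
  sos[1, 1:3] <- sos[1, 1:3] * k
  list(sos = sos)
}

#' Steady-state (step-response) initial conditions for one biquad section
#' @noRd
sos_zi <- function(sos) {
  zi <- matrix(0, nrow(sos), 2)
  scale <- 1
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]
    a <- sos[s, 4:6]
    h <- sum(b) / sum(a)             # DC gain of this section
    z2 <- b[3] - a[3] * h
    z1 <- b[2] - a[2] * h + z2
    zi[s, ] <- scale * c(z1, z2)
    scale <- scale * h
  }
  zi
}

#' Forward-backward (zero-phase) filtering with second-order sections
#' @noRd
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  nsec <- nrow(sos)
  padlen <- min(max(3 * (2 * nsec + 1), 256), n - 1)
  if (padlen < 1) stop_mobidt("filter_design", "signal too short to filter")
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- sos_zi(sos)
  y <- sosfilt_cpp(sos, ext, zi * ext[1])
  y <- rev(y)
  y <- sosfilt_cpp(sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Chebyshev Type II lowpass filter
#'
#' Designs a Chebyshev Type II lowpass meeting the given passband/stopband
#' specification and applies it forward and backward (zero net phase; the
#' effective stopband attenuation is doubled by the two passes). Matrices are
#' filtered row-wise (channels x time).
#'
#' @param x numeric vector, or channels x time matrix
#' @param sample_rate_hz sampling rate in Hz
#' @param band list with `type = "low"`, `edges_hz = c(passband, stopband)`,
#'   and optional `apass_db` (default 1) / `astop_db` (default 65)
#' @return filtered signal, same shape as `x`
#' @export
#' @examples
#' fs <- 512
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
#' y <- cheby2_zero_phase(x, fs, list(type = "low", edges_hz = c(45, 50)))
cheby2_zero_phase <- function(x, sample_rate_hz,
                              band = list(type = "low",
                                          edges_hz = c(45, 50),
                                          apass_db = 1, astop_db = 65)) {
  type <- band$type %||% "low"
  if (!identical(type, "low"))
    stop_mobidt("filter_design", "only lowpass designs are implemented")
  apass <- band$apass_db %||% 1
  astop <- band$astop_db %||% 65
  edges <- band$edges_hz
  if (length(edges) != 2 || any(!is.finite(edges)) || edges[1] >= edges[2])
    stop_mobidt("filter_design", "edges_hz must be c(passband, stopband), increasing")
  nyq <- sample_rate_hz / 2
  if (edges[2] >= nyq)
    stop_mobidt("filter_design", "filter edges must lie below the Nyquist frequency")
  wp <- edges[1] / nyq
  ws <- edges[2] / nyq
  n <- cheb2_order(wp, ws, apass, astop)
  sos <- cheb2_lowpass_sos(n, ws, astop)$sos
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- sos_filtfilt(sos, x[i, ])
    out
  } else sos_filtfilt(sos, x)
}

#' Anti-aliased integer-ratio downsampling
#'
#' Lowpass-filters (zero-phase Chebyshev Type II with stopband at the target
#' Nyquist and passband at 0.8 x target Nyquist) and then decimates by the
#' integer ratio `from_hz / to_hz`. DC is preserved exactly up to filter
#' precision.
#'
#' @param x numeric vector or channels x time matrix
#' @param from_hz,to_hz original and target sampling rates; the ratio must be
#'   an integer (e.g. 2048 -> 512)
#' @return downsampled signal of length `ceiling(n / ratio)`
#' @export
downsample <- function(x, from_hz = 2048, to_hz = 512) {
  ratio <- from_hz / to_hz
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop_mobidt("unsupported_ratio", "from_hz / to_hz must be a positive integer")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(x)
  target_nyq <- to_hz / 2
  band <- list(type = "low", edges_hz = c(0.8 * target_nyq, target_nyq),
               apass_db = 1, astop_db = 65)
  y <- cheby2_zero_phase(x, from_hz, band)
  if (is.matrix(y)) y[, seq(1, ncol(y), by = ratio), drop = FALSE]
  else y[seq(1, length(y), by = ratio)]
}
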
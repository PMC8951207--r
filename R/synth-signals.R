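# Band-limited complex Gaussian process with unit-variance real part.
# Spectrum is flat over [f_lo, f_hi] with raised-cosine edges (10% of the
# bandwidth); negative frequencies are zero, so the result is an analytic
# signal and its Arg is the exact instantaneous phase.
narrowband_analytic <- function(n, fs, f_lo, f_hi) {
  narrowband_analytic_multi(n, fs, f_lo, f_hi, 1)[, 1]
}

# batched variant: m independent processes as the columns of an n x m
# complex matrix (one inverse mvfft instead of m separate transforms)
narrowband_analytic_multi <- function(n, fs, f_lo, f_hi, m) {
  f <- (seq_len(n) - 1) * fs / n
  H <- numeric(n)
  pos <- f > 0 & f <= fs / 2
  bw <- f_hi - f_lo
  edge <- max(bw * 0.1, fs / n)
  ramp <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))
  H[pos] <- ramp((f[pos] - (f_lo - edge)) / edge) *
    ramp(((f_hi + edge) - f[pos]) / edge)
  H[f < f_lo - edge | f > f_hi + edge] <- 0
  if (all(H == 0)) stop("degenerate band: no spectral support")
  Z <- matrix(complex(real = stats::rnorm(n * m),
                      imaginary = stats::rnorm(n * m)), n, m) * H
  z <- stats::mvfft(Z, inverse = TRUE) / sqrt(n)
  s <- apply(z, 2, function(col) stats::sd(Re(col)))
  sweep(z, 2, s, "/")
}

# Smooth zero-mean unit-variance low-pass Gaussian process (cutoff Hz).
lowpass_process <- function(n, fs, cutoff) {
  Re(narrowband_analytic(n, fs, fs / n, cutoff))
}

# Solve for the phase-jitter scale s such that a stationary N(0, s^2)
# jitter W makes sign(sin(lag + W)) negative a fraction q of the time.
# Monotone in s; q = 0 gives s = 0.
jitter_scale <- function(lag, q) {
  stopifnot(q >= 0, q <= 0.5)
  if (q == 0) return(0)
  L <- abs(lag)
  if (sin(L) <= 1e-8) return(0)  # on the boundary the sign is never defined
  # P(sin(L + W) < 0) for W ~ N(0, s^2), accounting for phase wrap-around:
  # sin(L + W) < 0 iff L + W falls in (pi, 2pi) modulo 2pi
  occ <- function(s) {
    k <- -40:40
    sum(stats::pnorm((2 * pi - L + 2 * pi * k) / s) -
          stats::pnorm((pi - L + 2 * pi * k) / s)) - q
  }
  if (occ(20) <= 0) return(20)  # q at (or numerically at) its 0.5 ceiling
  stats::uniroot(occ, c(1e-6, 20), tol = 1e-10)$root
}

#' Specify phase-lag coupling for a synthetic recording
#'
#' @param band Band name or descriptor (Hz interval) of the oscillators.
#' @param pairs `data.frame` with columns `i`, `j` (channel labels),
#'   `lag` (radians, in (-pi, pi)) and `q` (sign-inconsistency in
#'   `[0, 0.5]`; the long-run PLI of the pair is `|1 - 2q|` while the pair
#'   is active). An optional integer column `slot` assigns each pair to
#'   one of `n_slots` rotating activation windows (intermittent coupling):
#'   pairs sharing a channel can then be placed in different slots so they
#'   do not dilute each other's shared-oscillator power.
#' @param base_amplitude Oscillator amplitude in microvolts.
#' @param noise_sd Amplitude (uV) of the independent band-limited noise
#'   added to every channel.
#' @param n_slots Number of activation slots (1 = all pairs always on).
#' @param slot_len_s Length of one activation window in seconds.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(band, pairs, base_amplitude = 10, noise_sd = 10,
                          n_slots = 1, slot_len_s = 2) {
  band <- as_band(band)
  if (nrow(pairs) > 0) {
    stopifnot(all(c("i", "j", "lag", "q") %in% names(pairs)))
    if (!all(pairs$lag > -pi & pairs$lag < pi)) {
      stop("pair lags must lie in (-pi, pi)")
    }
    if (!all(pairs$q >= 0 & pairs$q <= 0.5)) stop("q must lie in [0, 0.5]")
    if (is.null(pairs$slot)) pairs$slot <- 0L
    if (!all(pairs$slot %in% (seq_len(n_slots) - 1L))) {
      stop("pair slots must lie in 0..(n_slots - 1)")
    }
  }
  structure(list(band = band, pairs = pairs,
                 base_amplitude = base_amplitude, noise_sd = noise_sd,
                 n_slots = n_slots, slot_len_s = slot_len_s),
            class = "coupling_spec")
}

# 0/1 activation envelope for a slot: periodic square wave with 0.1-s
# raised-cosine ramps so switching stays narrowband-friendly
slot_envelope <- function(n, fs, slot, n_slots, slot_len_s) {
  if (n_slots <= 1) return(rep(1, n))
  t <- (seq_len(n) - 1) / fs
  period <- n_slots * slot_len_s
  u <- (t - slot * slot_len_s) %% period
  env <- as.numeric(u < slot_len_s)
  ramp <- 0.1
  rise <- u < ramp
  env[rise] <- 0.5 * (1 - cos(pi * u[rise] / ramp))
  fall <- u >= slot_len_s - ramp & u < slot_len_s
  env[fall] <- 0.5 * (1 - cos(pi * (slot_len_s - u[fall]) / ramp))
  env
}

#' Generate a synthetic EEG-like recording with known phase-lag structure
#'
#' Each coupled pair shares a band-limited oscillator; the second channel
#' carries the oscillator phase-shifted by `lag` plus a smooth stationary
#' Gaussian phase jitter calibrated so that `sign(sin(dphi))` is inverted a
#' fraction `q` of the time. The long-run PLI of the pair is therefore
#' exactly `|1 - 2q|`. The jitter is low-pass (slow relative to the band)
#' so that analytic-signal phase estimation can track it. Channels not in
#' any pair carry independent band-limited noise only.
#'
#' @param montage A [montage].
#' @param fs Sampling rate (Hz); must be at least 4x the band's upper edge.
#' @param duration_s Duration in seconds (>= 10).
#' @param coupling A [coupling_spec()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A [recording].
#' @export
generate_recording <- function(montage, fs, duration_s, coupling,
                               seed = NULL) {
  stopifnot(inherits(coupling, "coupling_spec"))
  band <- coupling$band
  if (fs < 4 * band$f_high) {
    stop("fs = ", fs, " too low for band upper edge ", band$f_high, " Hz")
  }
  if (duration_s < 10) stop("duration_s must be at least 10 s")
  if (!is.null(seed)) set.seed(seed)
  labels <- montage$labels
  pr <- coupling$pairs
  if (nrow(pr) > 0 && !all(c(pr$i, pr$j) %in% labels)) {
    stop("unknown channel label(s): ",
         paste(setdiff(c(pr$i, pr$j), labels), collapse = ", "))
  }
  n <- round(duration_s * fs)
  x <- matrix(0, length(labels), n, dimnames = list(labels, NULL))
  f0 <- (band$f_low + band$f_high) / 2
  wob_cut <- min(6, f0 / 3)
  np <- nrow(pr)
  if (np > 0) {
    zs <- narrowband_analytic_multi(n, fs, band$f_low, band$f_high, np)
    wob <- narrowband_analytic_multi(n, fs, fs / n, wob_cut, np)
    a <- coupling$base_amplitude
    for (p in seq_len(np)) {
      s <- jitter_scale(pr$lag[p], pr$q[p])
      W <- if (s > 0) s * Re(wob[, p]) else 0
      env <- slot_envelope(n, fs, if (is.null(pr$slot)) 0L else pr$slot[p],
                           coupling$n_slots, coupling$slot_len_s)
      x[pr$i[p], ] <- x[pr$i[p], ] + a * env * Re(zs[, p])
      x[pr$j[p], ] <- x[pr$j[p], ] +
        a * env * Re(zs[, p] * exp(-1i * (pr$lag[p] + W)))
    }
  }
  if (coupling$noise_sd > 0) {
    nz <- narrowband_analytic_multi(n, fs, band$f_low, band$f_high,
                                    length(labels))
    x <- x + coupling$noise_sd * t(Re(nz))
  }
  recording(x, fs, montage)
}
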
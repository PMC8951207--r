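#' Standard clinical EEG frequency bands
#'
#' Seven-band split used throughout: delta 0.5-4, theta 4-8, alpha-1 8-10,
#' alpha-2 10-13, beta-1 13-20, beta-2 20-30, gamma 30-45 Hz.
#'
#' @return Named list of band descriptors `list(name, f_low, f_high)`.
#' @export
eeg_bands <- function() {
  mk <- function(name, lo, hi) list(name = name, f_low = lo, f_high = hi)
  list(
    delta  = mk("delta", 0.5, 4),
    theta  = mk("theta", 4, 8),
    alpha1 = mk("alpha1", 8, 10),
    alpha2 = mk("alpha2", 10, 13),
    beta1  = mk("beta1", 13, 20),
    beta2  = mk("beta2", 20, 30),
    gamma  = mk("gamma", 30, 45)
  )
}

as_band <- function(band) {
  if (is.character(band)) {
    b <- eeg_bands()[[band]]
    if (is.null(b)) stop("unknown band name: ", band)
    return(b)
  }
  stopifnot(is.list(band), !is.null(band$f_low), !is.null(band$f_high))
  if (is.null(band$name)) band$name <- sprintf("%g-%gHz", band$f_low, band$f_high)
  band
}

# Linear-phase Hamming FIR applied by FFT convolution with exact integer
# group-delay compensation (order forced even), i.e. zero phase overall.
# x: channels x samples matrix. b: FIR coefficients, odd length.
apply_fir <- function(x, b) {
  nb <- length(b)
  stopifnot(nb %% 2 == 1)
  delay <- (nb - 1) / 2
  n <- ncol(x)
  nfft <- stats::nextn(n + nb - 1, c(2, 3))
  B <- stats::fft(c(b, numeric(nfft - nb)))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - n, nrow(x))))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  out <- t(y[(delay + 1):(delay + n), , drop = FALSE])
  dimnames(out) <- dimnames(x)
  out
}

# Choose an even FIR order from a transition bandwidth (Hz) via the
# Hamming-window rule order ~ 3.3 / normalized transition width, capped so
# the filter stays shorter than the signal.
fir_order <- function(fs, trans_bw, n_samples) {
  ord <- ceiling(3.3 * fs / trans_bw)
  ord <- min(ord, 4096, max(2, 2 * floor((n_samples - 1) / 3 / 2)))
  if (ord %% 2 == 1) ord <- ord + 1
  ord
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR with transition widths of 25% of each band edge
#' (floored at 0.2 Hz), applied with exact group-delay compensation so the
#' net response is zero phase. Phase-neutral filtering protects downstream
#' phase-lag-index estimates.
#'
#' @param rec A [recording].
#' @param f_low,f_high Band edges in Hz; must satisfy
#'   `0 < f_low < f_high <= fs/2`.
#' @return A filtered [recording].
#' @export
bandpass <- function(rec, f_low, f_high) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(f_low > 0 && f_low < f_high && f_high <= nyq)) {
    stop("band [", f_low, ", ", f_high, "] Hz invalid for fs = ", rec$fs)
  }
  tw <- max(0.2, 0.25 * f_low)
  ord <- fir_order(rec$fs, tw, ncol(rec$data))
  b <- signal::fir1(ord, c(f_low, f_high) / nyq, type = "pass")
  rec$data <- apply_fir(rec$data, as.numeric(b))
  rec
}

#' Zero-phase FIR notch filter
#'
#' Band-stop FIR (default 48-52 Hz) removing mains interference.
#'
#' @param rec A [recording].
#' @param f_center Notch center frequency in Hz.
#' @param half_width Half width of the stop band in Hz.
#' @return A filtered [recording].
#' @export
notch <- function(rec, f_center = 50, half_width = 2) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (f_center + half_width >= nyq) stop("notch band outside Nyquist range")
  ord <- fir_order(rec$fs, half_width, ncol(rec$data))
  b <- signal::fir1(ord, c(f_center - half_width, f_center + half_width) / nyq,
                    type = "stop")
  rec$data <- apply_fir(rec$data, as.numeric(b))
  rec
}

#' Cut a recording into consecutive non-overlapping epochs
#'
#' The trailing partial segment is dropped.
#'
#' @param rec A [recording].
#' @param epoch_len_s Epoch length in seconds (default 2).
#' @param band Optional band descriptor carried into the epoch set.
#' @return An [epoch_set].
#' @export
segment <- function(rec, epoch_len_s = 2, band = NULL) {
  stopifnot(inherits(rec, "recording"))
  spe <- round(epoch_len_s * rec$fs)
  n <- ncol(rec$data)
  if (n < spe) {
    stop("recording (", n / rec$fs, " s) shorter than one epoch (",
         epoch_len_s, " s)")
  }
  k <- floor(n / spe)
  ep <- array(rec$data[, seq_len(k * spe)], dim = c(nrow(rec$data), spe, k))
  dimnames(ep) <- list(rownames(rec$data), NULL, NULL)
  epoch_set(ep, rec$fs, rec$montage, band = band,
            log = sprintf("segment: %d epochs of %g s", k, epoch_len_s))
}

#' Re-reference epochs to the common average
#'
#' Subtracts the per-sample mean over channels, so every output sample has
#' zero channel mean. Idempotent.
#'
#' @param es An [epoch_set] with at least 2 channels.
#' @return The re-referenced [epoch_set].
#' @export
rereference_average <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$epochs)
  if (d[1] < 2) stop("average reference needs at least 2 channels")
  for (e in seq_len(d[3])) {
    m <- es$epochs[, , e]
    es$epochs[, , e] <- sweep(m, 2, colMeans(m))
  }
  append_log(es, "rereference: common average")
}

# shared decimation core: lowpass at 0.8 * target Nyquist, then pick every
# r-th sample. Integer ratios only.
decimate_matrix <- function(x, fs, target_fs) {
  r <- fs / target_fs
  if (abs(r - round(r)) > 1e-9) {
    stop("fs/target_fs must be an integer ratio (", fs, "/", target_fs, ")")
  }
  r <- round(r)
  if (r == 1) return(x)
  cutoff <- 0.8 * target_fs / 2
  ord <- fir_order(fs, 0.2 * target_fs / 2, ncol(x))
  b <- signal::fir1(ord, cutoff / (fs / 2), type = "low")
  y <- apply_fir(x, as.numeric(b))
  y[, seq(1, ncol(y), by = r), drop = FALSE]
}

#' Downsample a recording or epoch set
#'
#' Anti-alias low-pass filtering followed by decimation. Only integer
#' decimation ratios are supported; `target_fs == fs` is the identity.
#'
#' @param x A [recording] or [epoch_set].
#' @param target_fs Target sampling rate in Hz (default 512).
#' @return Same type as `x`, resampled.
#' @export
downsample <- function(x, target_fs = 512) {
  if (target_fs > x$fs) stop("upsampling requested (target_fs > fs)")
  if (target_fs == x$fs) return(x)
  if (inherits(x, "recording")) {
    x$data <- decimate_matrix(x$data, x$fs, target_fs)
    x$fs <- target_fs
    return(x)
  }
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$epochs)
  out <- NULL
  for (e in seq_len(d[3])) {
    y <- decimate_matrix(x$epochs[, , e, drop = TRUE], x$fs, target_fs)
    if (is.null(out)) out <- array(NA_real_, dim = c(d[1], ncol(y), d[3]))
    out[, , e] <- y
  }
  dimnames(out) <- list(dimnames(x$epochs)[[1]], NULL, NULL)
  x$epochs <- out
  x$fs <- target_fs
  append_log(x, sprintf("downsample: -> %g Hz", target_fs))
}

#' Reject epochs by absolute amplitude
#'
#' Drops every epoch containing any sample exceeding `limit_uv` in absolute
#' value on any channel. Retained samples are untouched; `kept_mask`
#' records the decision per original epoch.
#'
#' @param es An [epoch_set].
#' @param limit_uv Rejection limit in microvolts (default 80).
#' @return An [epoch_set] containing only the retained epochs.
#' @export
reject_amplitude <- function(es, limit_uv = 80) {
  stopifnot(inherits(es, "epoch_set"), limit_uv > 0)
  d <- dim(es$epochs)
  keep <- vapply(seq_len(d[3]),
                 function(e) max(abs(es$epochs[, , e])) <= limit_uv,
                 logical(1))
  es$epochs <- es$epochs[, , keep, drop = FALSE]
  es$kept_mask <- keep
  es <- append_log(es, sprintf("reject_amplitude: +/-%g uV, kept %d/%d",
                               limit_uv, sum(keep), length(keep)))
  if (!any(keep)) warning("all epochs rejected at +/-", limit_uv, " uV")
  es
}

#' Hjorth nearest-neighbour surface Laplacian
#'
#' Each channel is replaced by itself minus the mean of its montage
#' neighbours, attenuating spatially common (volume-conducted) signal.
#'
#' @param es An [epoch_set].
#' @param montage Montage supplying the neighbour table; defaults to the
#'   epoch set's own montage.
#' @return The spatially filtered [epoch_set].
#' @export
laplacian <- function(es, montage = es$montage) {
  stopifnot(inherits(es, "epoch_set"))
  labels <- dimnames(es$epochs)[[1]]
  if (is.null(labels)) labels <- montage$labels
  nch <- length(labels)
  L <- diag(nch)
  for (i in seq_len(nch)) {
    nb <- montage$neighbors[[labels[i]]]
    if (length(nb) == 0) stop("channel ", labels[i], " has no neighbors")
    idx <- match(nb, labels)
    if (anyNA(idx)) stop("neighbor(s) of ", labels[i], " missing from data")
    L[i, idx] <- -1 / length(idx)
  }
  for (e in seq_len(dim(es$epochs)[3])) {
    es$epochs[, , e] <- L %*% es$epochs[, , e]
  }
  append_log(es, "laplacian: Hjorth nearest-neighbor")
}

#' Full preprocessing pipeline for one band
#'
#' Runs the fixed order: broadband band-pass (0.5-45 Hz) + 50 Hz notch ->
#' band-pass to the requested band -> 2-s segmentation -> common average
#' reference -> downsample to 512 Hz -> amplitude rejection (+/-80 uV) ->
#' Hjorth Laplacian. Every step appends to the epoch set's provenance log.
#'
#' @param rec A [recording].
#' @param band Band name (see [eeg_bands()]) or band descriptor.
#' @param config A [run_config()] list supplying the constants.
#' @return An [epoch_set] ready for phase/PLI estimation.
#' @export
preprocess <- function(rec, band, config = run_config()) {
  band <- as_band(band)
  nyq <- rec$fs / 2
  hi <- min(config$broadband[2], nyq * 0.95)
  rec <- bandpass(rec, config$broadband[1], hi)
  if (config$notch_hz + 2 < nyq) rec <- notch(rec, config$notch_hz)
  rec <- bandpass(rec, band$f_low, band$f_high)
  es <- segment(rec, config$epoch_len_s, band = band)
  es$log <- c(sprintf("bandpass: %g-%g Hz + notch %g Hz + band %s",
                      config$broadband[1], hi, config$notch_hz, band$name),
              es$log)
  es <- rereference_average(es)
  es <- downsample(es, min(config$target_fs, rec$fs))
  es <- reject_amplitude(es, config$reject_uv)
  laplacian(es)
}
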
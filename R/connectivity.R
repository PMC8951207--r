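#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: negative frequencies zeroed, positive doubled.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel in an epoch set
#'
#' Phase of the analytic signal per channel per sample, for 1:1 phase
#' synchronization. Input should be narrowband for the analytic phase to be
#' meaningful. All-zero channels have no defined phase and raise an error.
#'
#' @param es An [epoch_set], band-limited.
#' @return A list with `phases` (channels x samples x epochs array of
#'   radians in (-pi, pi]), `fs` and `band`.
#' @export
instantaneous_phase <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$epochs)
  ph <- array(NA_real_, dim = d, dimnames = dimnames(es$epochs))
  for (e in seq_len(d[3])) {
    m <- es$epochs[, , e, drop = TRUE]
    if (any(apply(m, 1, function(r) all(r == 0)))) {
      stop("all-zero channel in epoch ", e, ": phase undefined")
    }
    for (i in seq_len(d[1])) ph[i, , e] <- Arg(analytic_signal(m[i, ]))
  }
  structure(list(phases = ph, fs = es$fs, band = es$band,
                 montage = es$montage),
            class = "phase_epochs")
}

#' Phase lag index of two phase series
#'
#' `PLI = |mean(sign(sin(phi_j - phi_k)))|`: the asymmetry of the
#' phase-difference distribution around zero. `sign(0)` contributes 0.
#' Insensitive to zero-lag (volume-conducted) coupling by construction.
#'
#' @param phase_j,phase_k Equal-length numeric vectors of phases (radians).
#' @return Scalar in `[0, 1]`.
#' @export
pli_pair <- function(phase_j, phase_k) {
  stopifnot(length(phase_j) == length(phase_k))
  if (length(phase_j) == 0) stop("empty phase series")
  abs(mean(sign(sin(phase_j - phase_k))))
}

# vectorized per-epoch PLI over all channel pairs.
# S, C: sin/cos of phases (channels x samples); jv, kv: pair indices.
pli_all_pairs <- function(S, C, jv, kv) {
  X <- S[jv, , drop = FALSE] * C[kv, , drop = FALSE] -
    C[jv, , drop = FALSE] * S[kv, , drop = FALSE]
  abs(rowMeans(sign(X)))
}

#' Phase-lag-index connectivity matrix
#'
#' PLI is computed per epoch (with a fraction of samples trimmed at each
#' epoch edge to suppress Hilbert edge transients) and averaged across
#' epochs. The result is symmetric with zero diagonal; entry (j,k) is the
#' mean per-epoch `pli_pair` of channels j and k.
#'
#' @param es An [epoch_set] (or the output of [instantaneous_phase()]).
#' @param edge_trim Fraction of samples discarded at each epoch edge
#'   (default 0.1).
#' @return A `pli_matrix`: channels x channels numeric matrix with
#'   attributes `band` and `n_epochs_used`.
#' @export
pli_matrix <- function(es, edge_trim = 0.1) {
  ph <- if (inherits(es, "phase_epochs")) es else instantaneous_phase(es)
  d <- dim(ph$phases)
  if (d[3] < 1) stop("no epochs retained; cannot estimate PLI")
  nch <- d[1]
  keep <- seq.int(floor(d[2] * edge_trim) + 1, d[2] - floor(d[2] * edge_trim))
  pairs <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  jv <- pairs[, 1]; kv <- pairs[, 2]
  acc <- numeric(nrow(pairs))
  for (e in seq_len(d[3])) {
    P <- ph$phases[, keep, e, drop = TRUE]
    acc <- acc + pli_all_pairs(sin(P), cos(P), jv, kv)
  }
  vals <- acc / d[3]
  M <- matrix(0, nch, nch,
              dimnames = list(dimnames(ph$phases)[[1]],
                              dimnames(ph$phases)[[1]]))
  M[cbind(jv, kv)] <- vals
  M[cbind(kv, jv)] <- vals
  structure(M, band = ph$band, n_epochs_used = d[3], class = "pli_matrix")
}

#' Read or write a PLI matrix as delimited text
#'
#' Tab-delimited square matrix with channel labels as header and row names.
#'
#' @param m A `pli_matrix` (or plain matrix).
#' @param path File path.
#' @return `read_pli_matrix` returns a numeric matrix.
#' @export
write_pli_matrix <- function(m, path) {
  utils::write.table(format(unclass(m), digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_pli_matrix
#' @export
read_pli_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}
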
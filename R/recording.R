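#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row names
#'   (if absent, taken from the montage) must match the montage labels.
#' @param fs Sampling rate in Hz.
#' @param montage A [montage] object describing the channels.
#' @return Object of class `recording`.
#' @export
recording <- function(data, fs, montage) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (!all(is.finite(data))) stop("recording data must be finite")
  if (is.null(rownames(data))) {
    if (nrow(data) != length(montage$labels)) {
      stop("data has ", nrow(data), " rows but montage has ",
           length(montage$labels), " labels")
    }
    rownames(data) <- montage$labels
  }
  if (!setequal(rownames(data), montage$labels)) {
    missing <- setdiff(montage$labels, rownames(data))
    stop("recording channels do not match montage; missing: ",
         paste(missing, collapse = ", "))
  }
  data <- data[montage$labels, , drop = FALSE]
  structure(list(data = data, fs = fs, montage = montage),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct an epoch set
#'
#' Fixed-length epochs of (optionally band-limited, spatially filtered)
#' signal: the input to phase and PLI estimation.
#'
#' @param epochs 3-d numeric array, channels x samples x epochs.
#' @param fs Sampling rate in Hz.
#' @param montage A [montage] object.
#' @param band Optional band descriptor, e.g. an element of [eeg_bands()].
#' @param kept_mask Logical vector over the original consecutive segments,
#'   `TRUE` where the segment survived artifact rejection.
#' @param log Character vector of provenance lines (one per pipeline step).
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, montage, band = NULL,
                      kept_mask = rep(TRUE, dim(epochs)[3]),
                      log = character()) {
  stopifnot(length(dim(epochs)) == 3, fs > 0)
  structure(list(epochs = epochs, fs = fs, montage = montage, band = band,
                 kept_mask = kept_mask, log = log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  bn <- if (is.null(x$band)) "broadband" else x$band$name
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz [%s]\n",
              d[3], d[1], d[2], x$fs, bn))
  invisible(x)
}

n_epochs <- function(x) dim(x$epochs)[3]

append_log <- function(x, line) {
  x$log <- c(x$log, line)
  x
}
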
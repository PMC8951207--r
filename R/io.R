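#' Write a recording as delimited text plus a YAML sidecar
#'
#' The data file is a tab-delimited channels x samples matrix (row names =
#' channel labels); the sidecar (`<path>.yaml`) records sampling rate,
#' channel order, and units so the pair round-trips losslessly.
#'
#' @param rec A [recording].
#' @param path Path of the data file; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  utils::write.table(format(rec$data, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = rownames(rec$data))
  yaml::write_yaml(list(fs = rec$fs, channels = rownames(rec$data),
                        unit = "uV"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a recording from delimited text plus a YAML sidecar
#'
#' The sidecar must provide `fs` and `channels`; an optional per-channel
#' `gain` vector rescales raw values to microvolts. Channels are mapped
#' onto the montage; a missing canonical channel is an explicit error.
#'
#' @param path Path of the data file (sidecar at `<path>.yaml`).
#' @param montage Montage to map channels onto (default [montage_1020()]).
#' @return A [recording].
#' @export
read_recording <- function(path, montage = montage_1020()) {
  side_path <- paste0(path, ".yaml")
  if (!file.exists(side_path)) stop("missing sidecar file: ", side_path)
  side <- yaml::read_yaml(side_path)
  if (is.null(side$fs)) stop("sidecar missing sampling rate 'fs'")
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  colnames(m) <- NULL
  if (!is.null(side$channels)) rownames(m) <- side$channels
  if (!is.null(side$gain)) m <- m * as.numeric(side$gain)
  missing <- setdiff(montage$labels, rownames(m))
  if (length(missing)) {
    stop("recording is missing canonical channel(s): ",
         paste(missing, collapse = ", "))
  }
  recording(m[montage$labels, , drop = FALSE], side$fs, montage)
}

#' Pipeline configuration
#'
#' Houses the fixed analysis constants: broadband filter 0.5-45 Hz, 50 Hz
#' notch, 2-s epochs, 512 Hz target rate, +/-80 uV rejection, sparsity
#' grid 0.05-0.40 in steps of 0.01, alpha = 0.05 with BH FDR within each
#' band x metric family, NBS primary t and permutation count, and the
#' metabolomics settings. Serialises round-trip losslessly through YAML.
#'
#' @param bands Named list of band descriptors (default [eeg_bands()]).
#' @param broadband Broadband filter edges in Hz.
#' @param notch_hz Mains notch frequency.
#' @param epoch_len_s Epoch length (s).
#' @param target_fs Downsampling target (Hz).
#' @param reject_uv Epoch rejection limit (uV).
#' @param sparsity Grid as `c(min, max, step)`.
#' @param alpha Significance level.
#' @param nbs_primary_t,nbs_n_perm Network-based-statistic settings.
#' @param metab_log,metab_scale,metab_components Metabolomics settings.
#' @param edge_trim Per-epoch edge fraction trimmed before PLI.
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(bands = eeg_bands(),
                       broadband = c(0.5, 45), notch_hz = 50,
                       epoch_len_s = 2, target_fs = 512, reject_uv = 80,
                       sparsity = c(0.05, 0.40, 0.01), alpha = 0.05,
                       nbs_primary_t = 2, nbs_n_perm = 1000,
                       metab_log = TRUE, metab_scale = "unit-variance",
                       metab_components = 2, edge_trim = 0.1, seed = 1) {
  stopifnot(broadband[1] > 0, broadband[1] < broadband[2],
            epoch_len_s > 0, target_fs > 0, reject_uv > 0,
            sparsity[1] > 0, sparsity[2] < 1, sparsity[3] > 0,
            alpha > 0, alpha < 1, nbs_n_perm >= 100, edge_trim >= 0,
            edge_trim < 0.5)
  structure(as.list(environment()), class = "run_config")
}

config_grid <- function(config) {
  sparsity_grid(config$sparsity[1], config$sparsity[2], config$sparsity[3])
}

#' Write / read a run configuration
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$broadband <- as.numeric(raw$broadband)
  raw$sparsity <- as.numeric(raw$sparsity)
  do.call(run_config, raw)
}

config_hash <- function(config) rlang::hash(unclass(config))
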
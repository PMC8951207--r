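#' Per-subject topology curves for one band
#'
#' Convenience chain: [preprocess()] -> [pli_matrix()] ->
#' [topology_curves()].
#'
#' @param rec A [recording].
#' @param band Band name or descriptor.
#' @param config A [run_config()].
#' @param subject Subject identifier copied into the curve table.
#' @param metrics Metrics to evaluate.
#' @return List with `pli` (the `pli_matrix`), `curves` (long table) and
#'   `n_epochs` retained.
#' @export
subject_topology <- function(rec, band, config = run_config(),
                             subject = NA_character_,
                             metrics = c("L_p", "C_c", "E_global",
                                         "E_local")) {
  es <- preprocess(rec, band, config)
  if (n_epochs(es) == 0) {
    return(list(pli = NULL, curves = NULL, n_epochs = 0))
  }
  M <- pli_matrix(es, edge_trim = config$edge_trim)
  cv <- topology_curves(M, config_grid(config), metrics, subject = subject)
  list(pli = M, curves = cv, n_epochs = n_epochs(es))
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, PLI connectivity, sparsity-grid topology, and
#' band-wise group statistics for every subject and requested band; when a
#' metabolite table (and optionally scores) is supplied, continues with the
#' VIP screen and the metabolite/score x topology correlation scans.
#' Result tables are written to `out_dir` together with a YAML run log
#' carrying the configuration hash, seed, input checksums, and per-stage
#' subject/epoch attrition. Identical config + inputs give identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param recordings Named list of [recording]s (names = subject IDs).
#' @param labels Factor of group labels (levels: group A first) aligned
#'   with `recordings`.
#' @param metabolites Optional [metabolite_table()] (sample IDs must match
#'   subject IDs).
#' @param scores Optional `data.frame` subject/score.
#' @param out_dir Output directory (created if absent).
#' @param bands Band names to analyse (default: all configured bands).
#' @return Invisibly, a list with the in-memory result tables.
#' @export
run_pipeline <- function(config, recordings, labels,
                         metabolites = NULL, scores = NULL,
                         out_dir = "results", bands = names(config$bands)) {
  stopifnot(length(recordings) == length(labels))
  if (is.null(names(recordings))) {
    names(recordings) <- sprintf("S%03d", seq_along(recordings))
  }
  labels <- factor(labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- config_grid(config)
  a_lvl <- levels(labels)[1]

  curves_all <- list()
  pli_store <- list()
  attrition <- list()
  for (bd in bands) {
    pli_store[[bd]] <- list()
    for (s in names(recordings)) {
      res <- tryCatch(
        subject_topology(recordings[[s]], bd, config, subject = s),
        error = function(e) {
          stop("stage 'topology' failed for subject ", s, " band ", bd,
               ": ", conditionMessage(e))
        })
      attrition[[paste(bd, s, sep = ":")]] <- res$n_epochs
      if (res$n_epochs == 0) next
      res$curves$band <- bd
      curves_all[[paste(bd, s, sep = ":")]] <- res$curves
      pli_store[[bd]][[s]] <- res$pli
    }
  }
  curves <- do.call(rbind, curves_all)
  rownames(curves) <- NULL
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(curves, "topology_curves.tsv")

  comparisons <- list(); averaged <- list(); nbs_out <- list()
  for (bd in bands) {
    subj_b <- names(pli_store[[bd]])
    grp <- labels[match(subj_b, names(recordings))]
    for (met in unique(curves$metric)) {
      d <- curves[curves$band == bd & curves$metric == met, ]
      M <- matrix(NA_real_, length(subj_b), length(grid),
                  dimnames = list(subj_b, NULL))
      M[cbind(match(d$subject, subj_b), match(d$sparsity, grid))] <- d$value
      avg <- average_significant(M[grp == a_lvl, , drop = FALSE],
                                 M[grp != a_lvl, , drop = FALSE],
                                 grid, config$alpha, band = bd,
                                 metric = met)
      comparisons[[paste(bd, met)]] <- avg$per_level
      if (!is.null(avg$comparison)) {
        out <- avg$comparison
        out$n_significant <- length(avg$significant)
        averaged[[paste(bd, met)]] <- out
      }
    }
    nbs_out[[bd]] <- nbs_test(pli_store[[bd]][grp == a_lvl],
                              pli_store[[bd]][grp != a_lvl],
                              primary_t = config$nbs_primary_t,
                              n_perm = config$nbs_n_perm,
                              seed = config$seed)
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL
  write_tsv(comparisons, "group_comparisons.tsv")
  if (length(averaged)) {
    averaged <- do.call(rbind, averaged)
    rownames(averaged) <- NULL
    write_tsv(averaged, "averaged_significant.tsv")
  } else averaged <- NULL
  nbs_summary <- do.call(rbind, lapply(names(nbs_out), function(bd) {
    x <- nbs_out[[bd]]
    if (length(x$component_sizes) == 0) {
      data.frame(band = bd, component = NA_integer_, size = 0,
                 p = NA_real_)
    } else {
      data.frame(band = bd, component = seq_along(x$component_sizes),
                 size = x$component_sizes, p = x$component_p)
    }
  }))
  write_tsv(nbs_summary, "nbs_components.tsv")

  screen <- scan <- score_cor <- NULL
  if (!is.null(metabolites)) {
    screen <- univariate_screen(metabolites,
                                n_components = config$metab_components,
                                log_transform = config$metab_log)
    write_tsv(as.data.frame(screen), "metabolite_screen.tsv")
    if (any(screen$selected)) {
      scan <- metabolite_topology_scan(metabolites, screen, curves)
      write_tsv(scan$map, "metabolite_topology_map.tsv")
      write_tsv(scan$argmax, "metabolite_topology_argmax.tsv")
      if (!is.null(scores)) {
        score_cor <- score_metabolite_correlation(scores, metabolites,
                                                  screen)
        write_tsv(score_cor, "score_metabolite_correlation.tsv")
      }
    }
  } else {
    message("no metabolite table supplied; metabolomics stages skipped")
  }

  log <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    alpha = config$alpha,
    fdr_family = "sparsity levels within band x metric",
    n_perm = config$nbs_n_perm,
    bands = bands,
    input_hash = rlang::hash(lapply(recordings, function(r) r$data)),
    n_subjects = length(recordings),
    epochs_retained = attrition,
    metabolomics_run = !is.null(metabolites)
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))

  invisible(list(curves = curves, comparisons = comparisons,
                 averaged = averaged, nbs = nbs_out, screen = screen,
                 scan = scan, score_correlation = score_cor, log = log))
}
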
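#' Spearman rank correlation with small-sample exact p
#'
#' Average ranks for ties; two-sided p from the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))`, replaced by the exact null
#' distribution for n <= 10 when there are no ties.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), non-constant.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector: rank correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate metabolite levels with topology across the sparsity grid
#'
#' For every selected feature x band x metric, Spearman correlation
#' against the per-subject metric at each sparsity level; the level of
#' maximum `|rho|` is recorded per (feature, band, metric). A max-statistic
#' permutation p across the scan is attached per (feature, band, metric)
#' as `p_scan`, alongside the conventional per-level raw p.
#'
#' @param table A [metabolite_table()] (subjects must match the curves).
#' @param screen A `screen_result` from [univariate_screen()]; only
#'   selected features are scanned. Pass `NULL` to scan all features.
#' @param curves Long-format topology table as returned by
#'   [topology_curves()] rows bound over subjects (columns subject, band,
#'   sparsity, metric, value).
#' @param n_perm Permutations for the max-|rho| family-wise p (0 = skip).
#' @param seed Seed for the permutation stream.
#' @return List with `map` (data.frame feature/band/metric/sparsity/rho/
#'   p/n) and `argmax` (data.frame with the max-|rho| sparsity and its
#'   permutation p).
#' @export
metabolite_topology_scan <- function(table, screen, curves, n_perm = 0,
                                     seed = 1) {
  feats <- if (is.null(screen)) table$features else
    screen$feature[screen$selected]
  if (length(feats) == 0) stop("no selected features to scan")
  subj <- table$sample_ids
  if (!all(curves$subject %in% subj)) {
    stop("subject ID mismatch between curves and metabolite table")
  }
  map_rows <- list(); arg_rows <- list()
  set.seed(seed)
  for (bd in unique(curves$band)) {
    for (met in unique(curves$metric)) {
      d <- curves[curves$band == bd & curves$metric == met, ]
      grid <- sort(unique(d$sparsity))
      # subjects x sparsity matrix of the metric
      M <- matrix(NA_real_, length(subj), length(grid),
                  dimnames = list(subj, NULL))
      M[cbind(match(d$subject, subj), match(d$sparsity, grid))] <- d$value
      if (anyNA(M)) stop("curves do not cover every subject x sparsity")
      for (f in feats) {
        xv <- table$intensities[, f]
        sc <- lapply(seq_along(grid), function(s) {
          if (stats::sd(M[, s]) == 0) return(list(rho = NA_real_,
                                                  p = NA_real_))
          spearman_cor(xv, M[, s])
        })
        rhos <- vapply(sc, `[[`, numeric(1), "rho")
        ps <- vapply(sc, `[[`, numeric(1), "p")
        if (all(is.na(rhos))) next
        best <- which.max(abs(rhos))
        p_scan <- NA_real_
        if (n_perm > 0) {
          rk_m <- apply(M, 2, rank)
          rk_m[, is.na(rhos)] <- NA_real_
          obs_max <- max(abs(rhos), na.rm = TRUE)
          cnt <- 0L
          for (b in seq_len(n_perm)) {
            rx <- rank(xv)[sample.int(length(xv))]
            pm <- max(abs(stats::cor(rx, rk_m)), na.rm = TRUE)
            if (pm >= obs_max) cnt <- cnt + 1L
          }
          p_scan <- (1 + cnt) / (1 + n_perm)
        }
        map_rows[[length(map_rows) + 1]] <- data.frame(
          feature = f, band = bd, metric = met, sparsity = grid,
          rho = rhos, p = ps, n = length(xv))
        arg_rows[[length(arg_rows) + 1]] <- data.frame(
          feature = f, band = bd, metric = met,
          argmax_sparsity = grid[best], rho = rhos[best], p = ps[best],
          p_scan = p_scan)
      }
    }
  }
  list(map = do.call(rbind, map_rows), argmax = do.call(rbind, arg_rows))
}

#' Correlate metabolite levels averaged over significant thresholds
#'
#' Threshold-averaged variant of the scan: the per-subject metric is first
#' averaged over a given sparsity set (typically the FDR-significant set
#' from [average_significant()]), then correlated with each feature.
#'
#' @inheritParams metabolite_topology_scan
#' @param sparsity_set Sparsity values to average over.
#' @return `data.frame` feature/band/metric/rho/p/n.
#' @export
metabolite_topology_averaged <- function(table, screen, curves,
                                         sparsity_set) {
  feats <- if (is.null(screen)) table$features else
    screen$feature[screen$selected]
  subj <- table$sample_ids
  rows <- list()
  for (bd in unique(curves$band)) {
    for (met in unique(curves$metric)) {
      d <- curves[curves$band == bd & curves$metric == met &
                    curves$sparsity %in% sparsity_set, ]
      if (nrow(d) == 0) next
      avg <- tapply(d$value, d$subject, mean)[subj]
      for (f in feats) {
        sc <- spearman_cor(table$intensities[, f], as.numeric(avg))
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, band = bd, metric = met, rho = sc$rho, p = sc$p,
          n = sc$n)
      }
    }
  }
  do.call(rbind, rows)
}

#' Correlate depression scores with selected metabolites
#'
#' Spearman rho and p per selected feature against the per-subject
#' depression score.
#'
#' @param scores `data.frame` with columns `subject` and `score`.
#' @param table A [metabolite_table()].
#' @param screen Optional `screen_result`; only selected features are used
#'   (`NULL` = all features).
#' @return `data.frame` feature/rho/p/n.
#' @export
score_metabolite_correlation <- function(scores, table, screen = NULL) {
  feats <- if (is.null(screen)) table$features else
    screen$feature[screen$selected]
  common <- intersect(scores$subject, table$sample_ids)
  if (length(common) < 3) stop("fewer than 3 matched subjects")
  sc_v <- scores$score[match(common, scores$subject)]
  rows <- lapply(feats, function(f) {
    r <- spearman_cor(sc_v, table$intensities[match(common,
                                                    table$sample_ids), f])
    data.frame(feature = f, rho = r$rho, p = r$p, n = r$n)
  })
  do.call(rbind, rows)
}

#' Correlate a pathway-level score with topology
#'
#' Pathway-level association realised as the first principal-component
#' score of the member features (log10, unit variance), correlated against
#' the per-subject metric at each sparsity level.
#'
#' @param table A [metabolite_table()].
#' @param members Feature names belonging to the pathway.
#' @param curves Long-format topology table (see
#'   [metabolite_topology_scan()]).
#' @return List as in [metabolite_topology_scan()] for the single
#'   synthetic "pathway" feature.
#' @export
pathway_topology_scan <- function(table, members, curves) {
  stopifnot(all(members %in% table$features))
  X <- scale(log10(table$intensities[, members, drop = FALSE]))
  pc1 <- stats::prcomp(X, center = FALSE, scale. = FALSE)$x[, 1]
  tab2 <- metabolite_table(matrix(exp(pc1), ncol = 1,
                                  dimnames = list(table$sample_ids,
                                                  "pathway_pc1")),
                           table$sample_ids, table$group, "pathway_pc1")
  metabolite_topology_scan(tab2, NULL, curves)
}
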
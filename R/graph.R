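#' The default sparsity grid
#'
#' Proportional thresholds 0.05, 0.06, ..., 0.40: exactly 36 levels.
#'
#' @param min,max,step Grid limits and step (unitless edge fractions).
#' @return Numeric vector of sparsity levels.
#' @export
sparsity_grid <- function(min = 0.05, max = 0.40, step = 0.01) {
  g <- seq(min, max, by = step)
  stopifnot(all(g > 0 & g < 1), !is.unsorted(g, strictly = TRUE))
  round(g, 10)
}

#' Threshold a weighted connectivity matrix into a binary graph
#'
#' Proportional ("sparsity") thresholding: the `round(S * N(N-1)/2)`
#' strongest off-diagonal weights become edges (round half up). Ties at the
#' cutoff are broken by lexicographic node-pair order, so the result is
#' deterministic. Alternatively, `mode = "absolute"` keeps every edge whose
#' weight exceeds `S` interpreted as an absolute threshold T.
#'
#' @param w Symmetric numeric matrix of edge weights (e.g. a `pli_matrix`).
#' @param S Sparsity level in (0, 1], or an absolute threshold when
#'   `mode = "absolute"`.
#' @param mode `"sparsity"` (default, proportional) or `"absolute"`.
#' @return Symmetric binary adjacency matrix with zero diagonal and
#'   attribute `sparsity`.
#' @export
binarize_by_sparsity <- function(w, S, mode = c("sparsity", "absolute")) {
  mode <- match.arg(mode)
  w <- unclass(w)
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[ut]
  A <- matrix(0L, n, n, dimnames = dimnames(w))
  if (mode == "absolute") {
    sel <- which(wt > S)
  } else {
    if (!(S > 0 && S <= 1)) stop("sparsity S must lie in (0, 1]")
    m <- floor(S * n * (n - 1) / 2 + 0.5)
    ord <- order(-wt, ut[, 1], ut[, 2])
    sel <- ord[seq_len(m)]
  }
  A[ut[sel, , drop = FALSE]] <- 1L
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  attr(A, "sparsity") <- S
  A
}

#' Shortest-path hop distances of a binary graph
#'
#' Breadth-first distances via boolean matrix powers; unreachable pairs are
#' `Inf`.
#'
#' @param A Symmetric binary adjacency matrix.
#' @return Numeric matrix of pairwise hop counts (0 on the diagonal).
#' @export
shortest_path_lengths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  A <- (unclass(A) != 0) * 1
  D[A > 0 & row(A) != col(A)] <- 1
  P <- A
  k <- 1
  while (any(is.infinite(D)) && k < n) {
    P <- (P %*% A > 0) * 1
    k <- k + 1
    new <- P > 0 & is.infinite(D)
    if (any(new)) D[new] <- k
  }
  D
}

#' Characteristic path length
#'
#' Mean hop distance over connected ordered node pairs. If any pair is
#' disconnected the mean is taken over connected pairs only and the result
#' carries attribute `fragmented = TRUE`.
#'
#' @param A Binary adjacency matrix (or a precomputed distance matrix via
#'   `D`).
#' @param D Optional distance matrix to reuse.
#' @return L_p (scalar, >= 1 when any edge exists), attribute `fragmented`.
#' @export
characteristic_path_length <- function(A, D = shortest_path_lengths(A)) {
  off <- D[row(D) != col(D)]
  if (!any(is.finite(off))) stop("graph has no edges: path length undefined")
  frag <- any(is.infinite(off))
  structure(mean(off[is.finite(off)]), fragmented = frag)
}

#' Mean clustering coefficient
#'
#' Mean over nodes of `2 t_i / (k_i (k_i - 1))` where `t_i` counts
#' triangles through node i; nodes of degree < 2 contribute 0.
#'
#' @param A Binary adjacency matrix.
#' @return C_c in `[0, 1]`.
#' @export
clustering_coefficient <- function(A) {
  A <- (unclass(A) != 0) * 1
  k <- rowSums(A)
  t_i <- diag(A %*% A %*% A) / 2
  ci <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  mean(ci)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse hop distance, with
#' `1/Inf = 0` for disconnected pairs.
#'
#' @inheritParams characteristic_path_length
#' @return E_global in `[0, 1]`.
#' @export
global_efficiency <- function(A, D = shortest_path_lengths(A)) {
  inv <- 1 / D
  diag(inv) <- 0
  n <- nrow(D)
  sum(inv[row(inv) != col(inv)]) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbours (paths constrained to that subgraph); nodes with fewer
#' than 2 neighbours contribute 0.
#'
#' @param A Binary adjacency matrix.
#' @return E_local in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  A <- (unclass(A) != 0) * 1
  n <- nrow(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    e[i] <- global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(e)
}

# all four metrics from one adjacency matrix, sharing one distance matrix
graph_metrics <- function(A, metrics = c("L_p", "C_c", "E_global", "E_local")) {
  need_d <- any(c("L_p", "E_global") %in% metrics)
  D <- if (need_d) shortest_path_lengths(A) else NULL
  out <- c()
  frag <- FALSE
  if ("L_p" %in% metrics) {
    lp <- characteristic_path_length(A, D)
    frag <- isTRUE(attr(lp, "fragmented"))
    out["L_p"] <- as.numeric(lp)
  }
  if ("C_c" %in% metrics) out["C_c"] <- clustering_coefficient(A)
  if ("E_global" %in% metrics) out["E_global"] <- global_efficiency(A, D)
  if ("E_local" %in% metrics) out["E_local"] <- local_efficiency(A)
  attr(out, "fragmented") <- frag
  out
}

#' Topology metrics over the sparsity grid
#'
#' Binarizes a PLI matrix at every grid level and evaluates the requested
#' global graph metrics, yielding one row per (sparsity, metric).
#'
#' @param w Weighted connectivity matrix (e.g. a `pli_matrix`).
#' @param grid Sparsity levels, default [sparsity_grid()].
#' @param metrics Which of `"L_p"`, `"C_c"`, `"E_global"`, `"E_local"` to
#'   compute.
#' @param subject,band Optional identifiers copied into the output.
#' @return Long-format `data.frame` with columns subject, band, sparsity,
#'   metric, value, fragmented.
#' @export
topology_curves <- function(w, grid = sparsity_grid(),
                            metrics = c("L_p", "C_c", "E_global", "E_local"),
                            subject = NA_character_, band = NA_character_) {
  if (is.na(band) && !is.null(attr(w, "band"))) band <- attr(w, "band")$name
  rows <- vector("list", length(grid))
  for (s in seq_along(grid)) {
    A <- binarize_by_sparsity(w, grid[s])
    m <- graph_metrics(A, metrics)
    rows[[s]] <- data.frame(subject = subject, band = band,
                            sparsity = grid[s], metric = names(m),
                            value = as.numeric(m),
                            fragmented = isTRUE(attr(m, "fragmented")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# matrix form used by the statistics stage: sparsity x metric
curve_matrix <- function(curves_df, metric) {
  d <- curves_df[curves_df$metric == metric, ]
  d$value[order(d$sparsity)]
}

# connected components of a binary graph; returns integer labels
graph_components <- function(A) {
  n <- nrow(A)
  A <- unclass(A) != 0
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}
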
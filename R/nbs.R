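# edge-wise pooled t statistics for a stacked edge matrix (edges x subjects)
edge_t <- function(E, is_a) {
  n1 <- sum(is_a); n2 <- sum(!is_a)
  m1 <- rowMeans(E[, is_a, drop = FALSE])
  m2 <- rowMeans(E[, !is_a, drop = FALSE])
  v1 <- rowSums((E[, is_a, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((E[, !is_a, drop = FALSE] - m2)^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
}

# size (edge count) of the largest connected suprathreshold component,
# plus the component memberships when requested
supra_components <- function(tvals, jv, kv, nch, primary_t, keep_edges = FALSE) {
  sel <- which(abs(tvals) > primary_t)
  if (length(sel) == 0) {
    return(list(max_size = 0L, sizes = integer(0), components = list()))
  }
  A <- matrix(0L, nch, nch)
  A[cbind(jv[sel], kv[sel])] <- 1L
  A[cbind(kv[sel], jv[sel])] <- 1L
  comp <- graph_components(A)
  edge_comp <- comp[jv[sel]]
  sizes <- table(edge_comp)
  comps <- list()
  if (keep_edges) {
    for (cc in names(sizes)) {
      idx <- sel[edge_comp == as.integer(cc)]
      comps[[length(comps) + 1]] <- data.frame(i = jv[idx], j = kv[idx],
                                               t = tvals[idx])
    }
    comps <- comps[order(-as.integer(sizes))]
  }
  list(max_size = max(as.integer(sizes)), sizes = sort(as.integer(sizes),
                                                       decreasing = TRUE),
       components = comps)
}

#' Permutation network-based statistic
#'
#' Edge-wise pooled t-tests between two groups of connectivity matrices;
#' edges with `|t|` above the primary threshold form suprathreshold
#' components, whose sizes (edge counts) are compared against the
#' permutation null of the maximum component size under group-label
#' shuffling. Controls family-wise error across edges at the component
#' level. Component p-values use the add-one estimator
#' `(1 + #{perm max >= observed}) / (1 + n_perm)`.
#'
#' @param mats_a,mats_b Lists (or 3-d arrays, channels x channels x
#'   subjects) of symmetric connectivity matrices per group (>= 2 each).
#' @param primary_t Primary t threshold applied edge-wise (default 2).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `nbs_result`: `components` (list of edge
#'   tables, largest first), `component_p`, `max_size`, `primary_t`,
#'   `n_perm`, `seed`.
#' @export
nbs_test <- function(mats_a, mats_b, primary_t = 2, n_perm = 1000,
                     seed = 1) {
  as_stack <- function(m) {
    if (is.array(m) && length(dim(m)) == 3) {
      lapply(seq_len(dim(m)[3]), function(i) m[, , i])
    } else m
  }
  mats_a <- as_stack(mats_a); mats_b <- as_stack(mats_b)
  if (length(mats_a) < 2 || length(mats_b) < 2) {
    stop("need at least 2 subjects per group")
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  nch <- nrow(mats_a[[1]])
  ut <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  jv <- ut[, 1]; kv <- ut[, 2]
  stack <- vapply(c(mats_a, mats_b), function(m) unclass(m)[ut],
                  numeric(nrow(ut)))
  n1 <- length(mats_a)
  is_a <- c(rep(TRUE, n1), rep(FALSE, length(mats_b)))
  if (any(apply(stack, 1, stats::sd) == 0)) {
    stop("degenerate (constant) edge across all subjects")
  }
  obs <- supra_components(edge_t(stack, is_a), jv, kv, nch, primary_t,
                          keep_edges = TRUE)
  set.seed(seed)
  perm_max <- integer(n_perm)
  nsub <- ncol(stack)
  for (b in seq_len(n_perm)) {
    pa <- logical(nsub)
    pa[sample.int(nsub, n1)] <- TRUE
    perm_max[b] <- supra_components(edge_t(stack, pa), jv, kv, nch,
                                    primary_t)$max_size
  }
  comp_p <- vapply(obs$sizes,
                   function(sz) (1 + sum(perm_max >= sz)) / (1 + n_perm),
                   numeric(1))
  structure(list(components = obs$components, component_p = comp_p,
                 component_sizes = obs$sizes, max_size = obs$max_size,
                 primary_t = primary_t, n_perm = n_perm, seed = seed,
                 perm_null = perm_max),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> primary |t| > %g, %d permutations\n",
              x$primary_t, x$n_perm))
  if (length(x$component_sizes) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$component_sizes)) {
      cat(sprintf("  component %d: %d edges, p = %.4f\n", i,
                  x$component_sizes[i], x$component_p[i]))
    }
  }
  invisible(x)
}
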
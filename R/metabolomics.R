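#' Construct a metabolite intensity table
#'
#' @param intensities Samples x features numeric matrix, strictly positive.
#' @param sample_ids Character vector of sample identifiers.
#' @param group Two-level factor (or coercible) of group labels.
#' @param features Feature names (unique).
#' @return Object of class `metabolite_table`.
#' @export
metabolite_table <- function(intensities, sample_ids, group, features) {
  stopifnot(is.matrix(intensities),
            nrow(intensities) == length(sample_ids),
            ncol(intensities) == length(features))
  if (any(intensities <= 0)) stop("intensities must be strictly positive")
  if (anyDuplicated(features)) stop("duplicate feature names")
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  dimnames(intensities) <- list(sample_ids, features)
  structure(list(intensities = intensities, sample_ids = sample_ids,
                 group = group, features = features),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("<metabolite_table> %d samples x %d features (groups: %s)\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(table(x$group), collapse = "/")))
  invisible(x)
}

#' Log-transform, centre and scale intensities
#'
#' Feature-wise preprocessing ahead of the latent-variable model:
#' optional log10 transform, mean centring, and unit-variance (or no)
#' scaling. Constant features scale to zero and are flagged via the
#' `constant` attribute.
#'
#' @param table A [metabolite_table()].
#' @param log_transform Apply log10 first (requires positive intensities).
#' @param scale `"unit-variance"` (default) or `"none"` (centring only).
#' @return Numeric samples x features matrix with attribute `constant`.
#' @export
preprocess_intensities <- function(table, log_transform = TRUE,
                                   scale = c("unit-variance", "none")) {
  scale <- match.arg(scale)
  X <- table$intensities
  if (log_transform) {
    if (any(X <= 0)) stop("log transform requires positive intensities")
    X <- log10(X)
  }
  X <- sweep(X, 2, colMeans(X))
  sds <- apply(X, 2, stats::sd)
  const <- sds < 1e-12
  if (scale == "unit-variance") {
    sds[const] <- 1
    X <- sweep(X, 2, sds, "/")
    X[, const] <- 0
  }
  attr(X, "constant") <- const
  X
}

#' PLS-DA by NIPALS
#'
#' Partial least squares discriminant analysis: the class label is coded
#' +/-1 and regressed on the preprocessed intensity matrix by sequential
#' NIPALS components with X-deflation. Initialisation is deterministic
#' (weights from the y-covariance direction), so fits are reproducible.
#' Optionally one orthogonal-signal-correction component (variation in X
#' orthogonal to y) is removed first.
#'
#' @param table A [metabolite_table()].
#' @param n_components Number of predictive latent components.
#' @param log_transform,scale Passed to [preprocess_intensities()].
#' @param osc Remove one class-orthogonal component before fitting.
#' @return Object of class `plsda_fit` with scores `T`, weights `W`,
#'   X-loadings `P`, y-loadings `q`, per-component explained y-variance
#'   `ssy`, and the preprocessed matrix dimensions.
#' @export
pls_da <- function(table, n_components = 2, log_transform = TRUE,
                   scale = "unit-variance", osc = FALSE) {
  X <- preprocess_intensities(table, log_transform, scale)
  grp <- table$group
  if (min(table(grp)) < 3) stop("need at least 3 samples per group")
  n <- nrow(X); p <- ncol(X)
  if (n_components >= min(n, p)) stop("n_components must be < min(n, p)")
  y <- ifelse(grp == levels(grp)[1], 1, -1)
  y <- y - mean(y)
  if (osc) {
    # one orthogonal-signal-correction pass: remove the dominant component
    # of X after projecting out the part of each column correlated with y
    Xo <- X - y %*% (crossprod(y, X) / sum(y^2))
    sv <- svd(Xo, nu = 1, nv = 1)
    t_o <- X %*% sv$v
    p_o <- crossprod(X, t_o) / sum(t_o^2)
    X <- X - t_o %*% t(p_o)
  }
  ssy_tot <- sum(y^2)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  ssy <- numeric(n_components)
  Xa <- X
  for (a in seq_len(n_components)) {
    w <- crossprod(Xa, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("no residual y-covariance at component ", a)
    w <- w / nw
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q[a] <- sum(y * t_a) / tt
    ssy[a] <- q[a]^2 * tt
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    Xa <- Xa - t_a %*% t(p_a)
  }
  structure(list(T = Tm, W = W, P = P, q = q, ssy = ssy,
                 explained_y = ssy / ssy_tot, n = n, p = p,
                 features = table$features, group = grp, osc = osc),
            class = "plsda_fit")
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a)` where
#' `SSY_a` is the y-variance explained by component a. By construction the
#' mean of `VIP^2` over features is exactly 1.
#'
#' @param model A [pls_da()] fit.
#' @param n_components How many components to use (default: all fitted;
#'   use 1 for first-component VIP).
#' @return Named numeric vector of per-feature VIP values (>= 0).
#' @export
vip <- function(model, n_components = ncol(model$W)) {
  stopifnot(inherits(model, "plsda_fit"))
  a_idx <- seq_len(n_components)
  ssy <- model$ssy[a_idx]
  if (sum(ssy) <= 0) stop("model explains no y-variance")
  W2 <- sweep(model$W[, a_idx, drop = FALSE]^2, 2,
              colSums(model$W[, a_idx, drop = FALSE]^2), "/")
  v <- sqrt(model$p * as.numeric(W2 %*% ssy) / sum(ssy))
  names(v) <- model$features
  v
}

#' Univariate + multivariate metabolite screen
#'
#' Per-feature two-sample pooled t-test on log10 intensities, BH-adjusted
#' p-values across features, fold change on raw group means
#' (group A / group B), PLS-DA VIP, and the selection rule
#' `VIP > 1 AND p < 0.05` (raw p, with the BH-adjusted p reported
#' alongside).
#'
#' @param table A [metabolite_table()].
#' @param n_components Components for the PLS-DA model (VIP uses all).
#' @param vip_threshold,alpha Selection cutoffs.
#' @param log_transform Run the t-tests on log10 intensities (default).
#' @return `data.frame` (class `screen_result`) with one row per feature:
#'   feature, VIP, t, p, p_fdr, fold_change, selected.
#' @export
univariate_screen <- function(table, n_components = 2, vip_threshold = 1,
                              alpha = 0.05, log_transform = TRUE) {
  grp <- table$group
  a_lvl <- levels(grp)[1]
  X <- table$intensities
  Xt <- if (log_transform) log10(X) else X
  res <- lapply(seq_len(ncol(X)), function(j) {
    tt <- ttest_ind(Xt[grp == a_lvl, j], Xt[grp != a_lvl, j])
    c(t = tt$t, p = tt$p)
  })
  res <- do.call(rbind, res)
  fc <- colMeans(X[grp == a_lvl, , drop = FALSE]) /
    colMeans(X[grp != a_lvl, , drop = FALSE])
  model <- pls_da(table, n_components = n_components,
                  log_transform = log_transform)
  v <- vip(model)
  out <- data.frame(
    feature = table$features,
    VIP = as.numeric(v),
    t = res[, "t"],
    p = res[, "p"],
    p_fdr = fdr_bh(res[, "p"]),
    fold_change = as.numeric(fc),
    selected = as.numeric(v) > vip_threshold & res[, "p"] < alpha,
    row.names = NULL
  )
  class(out) <- c("screen_result", "data.frame")
  attr(out, "model") <- model
  out
}

#' Read or write a metabolite table as delimited text
#'
#' Tab-delimited with a header row of feature names; first column sample
#' ID, second column group label.
#'
#' @param table A [metabolite_table()].
#' @param path File path.
#' @return `read_metabolite_table` returns a [metabolite_table()].
#' @export
write_metabolite_table <- function(table, path) {
  df <- data.frame(sample = table$sample_ids, group = table$group,
                   format(table$intensities, digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_table
#' @export
read_metabolite_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(X) <- "double"
  metabolite_table(X, df[[1]], df[[2]], colnames(X))
}
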
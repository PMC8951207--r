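random_table <- function(n = 20, p = 10, seed = 1) {
  set.seed(seed)
  X <- exp(matrix(rnorm(n * p, 10, 0.5), n, p))
  metabolite_table(X, sprintf("S%02d", 1:n),
                   rep(c("A", "B"), each = n / 2), sprintf("f%02d", 1:p))
}

test_that("intensity preprocessing centres, scales, and flags constant features", {
  tab <- random_table()
  X <- preprocess_intensities(tab)
  expect_lt(max(abs(colMeans(X))), 1e-9)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-9)
  Xc <- preprocess_intensities(tab, scale = "none")
  expect_lt(max(abs(colMeans(Xc))), 1e-9)
  expect_false(all(abs(apply(Xc, 2, sd) - 1) < 1e-6))

  tab2 <- tab
  tab2$intensities[, 3] <- 5
  X2 <- preprocess_intensities(tab2)
  expect_true(attr(X2, "constant")[3])
  expect_equal(unname(X2[, 3]), rep(0, 20))
})

test_that("PLS-DA concentrates weight on a perfectly separating feature", {
  set.seed(2)
  n <- 24
  grp <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 8, 0, 1), n, 8)
  # make the noise features exactly class-orthogonal so the separating
  # feature carries all the y-covariance
  for (j in 2:8) X[, j] <- X[, j] - ave(X[, j], grp)
  X[, 1] <- rep(c(2, -2), each = n / 2) + rnorm(n, 0, 0.05)
  tab <- metabolite_table(exp((X + 10) / 5), sprintf("S%02d", 1:n),
                          grp, sprintf("f%d", 1:8))
  fit <- pls_da(tab, 2)
  expect_gt(abs(fit$W[1, 1]), 0.99)
  v <- vip(fit)
  expect_gt(v[1], 2)
})

test_that("a class label unrelated to the data explains almost no y-variance", {
  set.seed(3)
  X <- exp(matrix(rnorm(100 * 5, 8, 0.3), 100, 5))
  tab <- metabolite_table(X, sprintf("S%03d", 1:100),
                          rep(c("A", "B"), each = 50), sprintf("f%d", 1:5))
  fit <- pls_da(tab, 2)
  expect_lt(sum(fit$explained_y), 0.12)
})

test_that("PLS-DA scores and weights match the mixOmics reference up to sign", {
  skip_if_not_installed("mixOmics")
  tab <- random_table(n = 24, p = 12, seed = 9)
  fit <- pls_da(tab, 2)
  X <- preprocess_intensities(tab)
  ref <- mixOmics::pls(X, as.numeric(tab$group == "A") -
                         mean(tab$group == "A"),
                       ncomp = 2, scale = FALSE, mode = "regression")
  for (a in 1:2) {
    r_scores <- abs(cor(fit$T[, a], ref$variates$X[, a]))
    r_weights <- abs(cor(fit$W[, a], ref$loadings$X[, a]))
    expect_gt(r_scores, 0.999)
    expect_gt(r_weights, 0.999)
  }
})

test_that("VIP satisfies its mean-square identity and its limiting cases", {
  tab <- random_table(n = 20, p = 15, seed = 4)
  fit <- pls_da(tab, 2)
  v <- vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  expect_true(all(v >= 0))

  # identical copies of one feature are exchangeable: every VIP is 1
  set.seed(5)
  base <- rnorm(20, 10, 1)
  Xd <- exp(matrix(rep(base, 6), 20, 6) + 1e-6)
  tabd <- metabolite_table(Xd, sprintf("S%02d", 1:20),
                           rep(c("A", "B"), 10), sprintf("f%d", 1:6))
  fitd <- pls_da(tabd, 1)
  expect_equal(unname(vip(fitd)), rep(1, 6), tolerance = 1e-6)

  # single informative feature among p: its VIP approaches sqrt(p)
  set.seed(6)
  n <- 40; p <- 10
  grp <- rep(c("A", "B"), each = n / 2)
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(p)) X[, j] <- X[, j] - ave(X[, j], grp)
  X[, 4] <- y + rnorm(n, 0, 1e-3)
  tabs <- metabolite_table(exp(X), sprintf("S%02d", 1:n), grp,
                           sprintf("f%d", 1:p))
  fits <- pls_da(tabs, 1)
  expect_equal(unname(vip(fits))[4], sqrt(p), tolerance = 0.01)
})

test_that("the VIP > 1 & p < 0.05 screen recovers planted features and controls nulls", {
  # planted: 5 of 50 features shifted by one natural-log unit
  recovered <- integer(5)
  for (s in 1:5) {
    spec <- synth_cohort_spec(n_group_a = 20, n_group_b = 20,
                              log_fold_change = 1.0, seed = 100 + s)
    coh <- generate_cohort(spec, eeg = FALSE)
    scr <- univariate_screen(coh$metabolites)
    recovered[s] <- sum(scr$selected[coh$truth$affected])
    # planted direction: fold change above 1 for up-shifted features
    expect_true(all(scr$fold_change[coh$truth$affected] > 1))
  }
  expect_gte(median(recovered), 4)

  # null: no planted effects anywhere
  fp <- numeric(5)
  for (s in 1:5) {
    spec0 <- synth_cohort_spec(n_group_a = 20, n_group_b = 20,
                               log_fold_change = 0,
                               rewire_a = c(2, 5), rewire_b = c(2, 5),
                               score_link = list(feature = 1, rho = 0),
                               seed = 200 + s)
    coh0 <- generate_cohort(spec0, eeg = FALSE)
    scr0 <- univariate_screen(coh0$metabolites)
    fp[s] <- mean(scr0$selected)
  }
  expect_lte(mean(fp), 0.10)
})

test_that("fold change of an unshifted feature stays near 1", {
  spec <- synth_cohort_spec(n_group_a = 30, n_group_b = 30, seed = 77)
  coh <- generate_cohort(spec, eeg = FALSE)
  scr <- univariate_screen(coh$metabolites)
  unaffected <- setdiff(seq_len(50), c(coh$truth$affected,
                                       coh$truth$linked_feature))
  expect_lt(median(abs(log(scr$fold_change[unaffected]))), 0.25)
})

test_that("screen output satisfies its structural invariants", {
  tab <- random_table(n = 24, p = 12, seed = 11)
  scr <- univariate_screen(tab)
  expect_equal(mean(scr$VIP^2), 1, tolerance = 1e-8)
  expect_true(all(scr$p_fdr >= scr$p))
  expect_equal(scr$selected, scr$VIP > 1 & scr$p < 0.05)
})
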
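test_that("generated recordings are byte-identical under a fixed seed", {
  m <- montage_1020()
  cs <- coupling_spec("beta1", data.frame(i = "F3", j = "P4",
                                          lag = pi / 2, q = 0.1),
                      base_amplitude = 8, noise_sd = 2)
  r1 <- generate_recording(m, 512, 10, cs, seed = 42)
  r2 <- generate_recording(m, 512, 10, cs, seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(m, 512, 10, cs, seed = 43)
  expect_false(identical(r1$data, r3$data))
})

test_that("cohort generation is reproducible and intensities are strictly positive", {
  spec <- synth_cohort_spec(n_group_a = 3, n_group_b = 3, fs = 512,
                            duration_s = 10, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$metabolites$intensities, c2$metabolites$intensities)
  expect_identical(c1$recordings[[2]]$data, c2$recordings[[2]]$data)
  expect_identical(c1$scores, c2$scores)
  expect_true(all(c1$metabolites$intensities > 0))
})

test_that("invalid coupling and cohort specifications are rejected", {
  m <- montage_1020()
  expect_error(coupling_spec("beta1",
                             data.frame(i = "F3", j = "P4", lag = 4, q = 0.1)),
               "lags")
  expect_error(coupling_spec("beta1",
                             data.frame(i = "F3", j = "P4", lag = 1, q = 0.7)),
               "q must")
  cs <- coupling_spec("beta1", data.frame(i = "XX", j = "P4",
                                          lag = 1, q = 0.1))
  expect_error(generate_recording(m, 512, 10, cs), "unknown channel")
  cs2 <- coupling_spec("gamma", data.frame(i = "F3", j = "P4",
                                           lag = 1, q = 0.1))
  expect_error(generate_recording(m, 100, 10, cs2), "too low")
  expect_error(generate_recording(m, 512, 5,
                                  coupling_spec("beta1",
                                                data.frame(i = "F3", j = "P4",
                                                           lag = 1, q = 0.1))),
               "duration")
  expect_error(synth_cohort_spec(n_metabolites = 10,
                                 affected_features = 9:11), "affected")
  expect_error(synth_cohort_spec(score_link = list(feature = 1, rho = 1.4)),
               "rho")
})

test_that("the phase-jitter process hits the requested sign-inconsistency occupancy", {
  # Monte-Carlo oracle: the long-run fraction of sign(sin(lag + W)) < 0
  # must equal q, which makes the PLI target |1 - 2q| by construction
  set.seed(8)
  n <- 200000
  for (q in c(0.05, 0.1, 0.25, 0.4)) {
    for (lag in c(pi / 3, pi / 2)) {
      s <- plinet:::jitter_scale(lag, q)
      W <- s * rnorm(n)  # stationary marginal of the low-pass process
      occ <- mean(sin(lag + W) < 0)
      expect_lt(abs(occ - q), 0.01)
    }
  }
  expect_equal(plinet:::jitter_scale(pi / 2, 0), 0)
})

test_that("a zero log-fold-change leaves group mean intensities equal in expectation", {
  spec <- synth_cohort_spec(n_group_a = 40, n_group_b = 40,
                            log_fold_change = 0,
                            rewire_a = c(2, 5), rewire_b = c(2, 5),
                            score_link = list(feature = 1, rho = 0),
                            seed = 9)
  coh <- generate_cohort(spec, eeg = FALSE)
  lx <- log(coh$metabolites$intensities)
  gap <- colMeans(lx[coh$labels == "A", ]) - colMeans(lx[coh$labels == "B", ])
  # each feature gap ~ N(0, sigma^2 * 2/40): mean over 50 features near 0
  expect_lt(abs(mean(gap)), 3 * 0.5 * sqrt(2 / 40) / sqrt(50))
  expect_lt(max(abs(gap)), 4 * 0.5 * sqrt(2 / 40))
})

test_that("the planted network link lands near the target Spearman correlation", {
  in_band <- logical(30)
  for (s in 1:30) {
    spec <- synth_cohort_spec(n_group_a = 20, n_group_b = 20, seed = 300 + s)
    coh <- generate_cohort(spec, eeg = FALSE)
    r <- cor(coh$metabolites$intensities[, coh$truth$linked_feature],
             coh$truth$eg_true, method = "spearman")
    in_band[s] <- r >= 0.45 && r <= 0.85
  }
  expect_gte(mean(in_band), 0.9)
})

test_that("depression-like scores increase with the rewiring probability", {
  spec <- synth_cohort_spec(n_group_a = 25, n_group_b = 25, seed = 13)
  coh <- generate_cohort(spec, eeg = FALSE)
  expect_gt(cor(coh$scores$score, coh$truth$rewire, method = "spearman"), 0.7)
  expect_gt(mean(coh$scores$score[coh$labels == "A"]),
            mean(coh$scores$score[coh$labels == "B"]))
})
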
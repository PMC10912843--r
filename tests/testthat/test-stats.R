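test_that("the pooled t test matches hand computation on printed vectors", {
  dynA <- mock_dynamics(matrix(c(1, 2, 3), 1))
  dynB <- mock_dynamics(matrix(c(4, 5, 6), 1))
  cmp <- compare_metric(dynA, dynB, "fractional_occupancy",
                        variant = "student")
  expect_lt(abs(cmp$t_statistic - (-3.674)), 1e-3)
  expect_lt(abs(cmp$p_raw - 0.0214), 1e-3)

  # classical pooled-variance formula on random vectors, to 1e-10
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), mean = 0.3)
    cmp2 <- compare_metric(mock_dynamics(matrix(a, 1)),
                           mock_dynamics(matrix(b, 1)),
                           "fractional_occupancy")
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(cmp2$t_statistic, t_hand, tolerance = 1e-10)
    expect_equal(cmp2$p_raw, 2 * pt(-abs(t_hand), na + nb - 2),
                 tolerance = 1e-10)
  }
})

test_that("identical groups give null statistics for every state", {
  set.seed(6)
  vals <- matrix(runif(4 * 8), 4)
  cmp <- compare_metric(mock_dynamics(vals), mock_dynamics(vals),
                        "fractional_occupancy")
  expect_equal(cmp$t_statistic, rep(0, 4))
  expect_equal(cmp$p_raw, rep(1, 4))
  expect_equal(cmp$q_fdr, rep(1, 4))
})

test_that("NaN metric values are excluded pairwise with recorded n", {
  vals <- matrix(runif(2 * 6), 2)
  vals[2, 1:2] <- NaN
  cmp <- compare_metric(mock_dynamics(vals),
                        mock_dynamics(matrix(runif(2 * 6), 2)),
                        "interval", group_names = c("g1", "g2"))
  expect_identical(cmp$n_g1, c(6L, 4L))
  expect_identical(cmp$n_g2, c(6L, 6L))
  expect_false(any(is.na(cmp$p_raw)))
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # q >= p and monotone in the order statistics, on random inputs
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- fdr_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("permutation test is exact under exchangeable identical groups", {
  set.seed(13)
  sim <- simulate_cohort(k3_spec(31, n_per_group = c(patient = 6,
                                                     control = 6),
                                 n_timepoints = 120))
  dyn <- cohort_dynamics(sim$true_paths, 3, 2)
  res <- permutation_test_transitions(dyn[1:6], dyn[1:6],
                                      n_permutations = 99, seed = 2)
  expect_true(all(res$observed_diff == 0))
  expect_true(all(res$p_perm == 1))
})

test_that("permutation p values respect group-label symmetry and bounds", {
  sim <- simulate_cohort(k3_spec(37, n_per_group = c(patient = 8,
                                                     control = 8),
                                 n_timepoints = 150))
  dyn <- cohort_dynamics(sim$true_paths, 3, 2)
  a <- dyn[1:8]; b <- dyn[9:16]
  r1 <- permutation_test_transitions(a, b, n_permutations = 499, seed = 7)
  r2 <- permutation_test_transitions(b, a, n_permutations = 499, seed = 7)
  expect_equal(r2$observed_diff, -r1$observed_diff, tolerance = 1e-12)
  # equal group sizes: the shuffle null is symmetric in distribution, so
  # the two orientations agree up to Monte-Carlo noise
  expect_equal(r2$p_perm, r1$p_perm, tolerance = 0.1)
  expect_true(all(r1$p_perm >= 1 / 500 & r1$p_perm <= 1))
  # determinism
  r3 <- permutation_test_transitions(a, b, n_permutations = 499, seed = 7)
  expect_identical(r3$p_perm, r1$p_perm)
})

test_that("partial Spearman reproduces rank-correlation ground truths", {
  # perfect concordance under any monotone transform
  x <- c(0.3, 1.2, 5, 7, 11)
  r <- partial_spearman(x, exp(x))
  expect_equal(r$rho, 1)

  # printed 5-point example, cross-checked against stats::cor
  x5 <- 1:5; y5 <- c(2, 1, 4, 3, 5)
  r5 <- partial_spearman(x5, y5)
  expect_equal(r5$rho, cor(x5, y5, method = "spearman"))
  expect_equal(r5$rho, 0.8)

  # independent normals: rho near zero
  set.seed(15)
  rn <- partial_spearman(rnorm(2000), rnorm(2000))
  expect_lt(abs(rn$rho), 0.06)

  # partialing out a shared covariate removes a spurious correlation
  set.seed(16)
  z <- rnorm(300)
  a <- z + rnorm(300, sd = 0.4)
  b <- z + rnorm(300, sd = 0.4)
  raw <- partial_spearman(a, b)
  adj <- partial_spearman(a, b, covariates = cbind(z = z))
  expect_gt(raw$rho, 0.6)
  expect_lt(abs(adj$rho), 0.2)

  expect_error(partial_spearman(1:10, 1:10,
                                covariates = cbind(1:10, 2 * (1:10))),
               "rank-deficient")
  expect_error(partial_spearman(1:3, 1:3, covariates = cbind(1:3)),
               "at least")
})

test_that("MoCA grouping uses the impairment cutoff with boundary logging", {
  meta <- data.frame(subject_id = sprintf("s%d", 1:5),
                     moca = c(20, 25, 26, 27, NA))
  g <- moca_impairment_groups(meta)
  expect_identical(g$impaired, c("s1", "s2"))
  expect_identical(g$unimpaired, c("s3", "s4"))
  expect_identical(g$n_boundary, 1L)
})

test_that("score correlations run per state with covariate adjustment", {
  sim <- simulate_cohort(default_paper_like_spec(0.12, seed = 77))
  K <- sim$spec$n_states
  dyn <- cohort_dynamics(sim$true_paths, K, 2)
  tab <- correlate_with_score(dyn, sim$cohort$meta,
                              "fractional_occupancy")
  expect_identical(nrow(tab), K)
  expect_true(all(abs(tab$rho) <= 1, na.rm = TRUE))
  # the simulator links MoCA to occupancy of state 3: positive rho there
  expect_gt(tab$rho[tab$state == "3"], 0)
})
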
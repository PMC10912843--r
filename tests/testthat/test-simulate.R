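test_that("an absorbing chain yields constant paths", {
  A <- diag(2)
  sp <- ground_truth_spec(2, 2, 50, 2, A, c(1, 0),
                          matrix(0, 2, 2), rep(list(diag(2)), 2),
                          n_per_group = c(patient = 2, control = 2),
                          seed = 3)
  sim <- simulate_cohort(sp)
  for (p in sim$true_paths) expect_true(all(p == 1L))
})

test_that("state frequencies of a uniform chain obey the law of large numbers", {
  K <- 3
  A <- matrix(1 / K, K, K)
  sp <- ground_truth_spec(K, 2, 30000, 2, A, rep(1 / K, K),
                          matrix(0, K, 2), rep(list(diag(2)), K),
                          n_per_group = c(patient = 1), seed = 5)
  sim <- simulate_cohort(sp)
  freq <- fractional_occupancy(sim$true_paths[[1L]], K)
  expect_true(all(abs(freq - 1 / K) < 0.01))
})

test_that("simulation is a deterministic function of the spec seed", {
  sp <- k3_spec(9, jitter = 0.2)
  sim1 <- simulate_cohort(sp)
  sim2 <- simulate_cohort(sp)
  expect_identical(sim1$true_paths, sim2$true_paths)
  expect_identical(lapply(sim1$cohort$series, `[[`, "data"),
                   lapply(sim2$cohort$series, `[[`, "data"))
  expect_identical(sim1$cohort$meta, sim2$cohort$meta)
})

test_that("without effects or jitter every subject shares the base matrix", {
  sp <- k3_spec(4, jitter = 0)
  sim <- simulate_cohort(sp)
  for (A in sim$true_transitions)
    expect_identical(A, sp$base_transition)
})

test_that("empirical transition frequencies of a long chain converge to truth", {
  K <- 3
  A <- matrix(c(.8, .15, .05,
                .1, .8, .1,
                .05, .25, .7), 3, 3, byrow = TRUE)
  sp <- ground_truth_spec(K, 2, 1e5, 2, A, rep(1 / K, K),
                          matrix(0, K, 2), rep(list(diag(2)), K),
                          n_per_group = c(patient = 1), seed = 12)
  sim <- simulate_cohort(sp)
  emp <- subject_transition_matrix(sim$true_paths[[1L]], K)$probs
  expect_lt(max(abs(emp - A)), 0.01)
})

test_that("conditional observation means recover the state means", {
  sp <- k3_spec(8, n_timepoints = 2000,
                n_per_group = c(patient = 1, control = 1))
  sim <- simulate_cohort(sp)
  obs <- t(sim$cohort$series[[1L]]$data)
  path <- sim$true_paths[[1L]]
  for (k in 1:3) {
    n_k <- sum(path == k)
    se <- 1 / sqrt(n_k)  # unit innovation variance
    est <- colMeans(obs[path == k, , drop = FALSE])
    expect_true(all(abs(est - sp$state_means[k, ]) < 3 * se + 0.05))
  }
})

test_that("group effects rescale the targeted entry with row renormalization", {
  sp <- k3_spec(4)
  sp$group_effects <- list(list(group = "patient", from = 1L, to = 2L,
                                factor = 2))
  A_pat <- dynstates:::subject_transition(sp, "patient")
  A_con <- dynstates:::subject_transition(sp, "control")
  expect_identical(A_con, sp$base_transition)
  b <- sp$base_transition[1, 2]
  expect_equal(A_pat[1, 2], 2 * b / (1 + b), tolerance = 1e-12)
  expect_equal(rowSums(A_pat), rep(1, 3), tolerance = 1e-12)
  expect_equal(A_pat[2:3, ], sp$base_transition[2:3, ])
})

test_that("the full-scale default spec has the study dimensions", {
  sp <- default_paper_like_spec(1)
  expect_identical(sp$n_states, 12L)
  expect_identical(sp$n_regions, 116L)
  expect_identical(sp$n_timepoints, 220L)
  expect_equal(sp$tr_seconds, 2)
  expect_identical(unname(sp$n_per_group[c("patient", "control")]),
                   c(71L, 57L))

  sp01 <- default_paper_like_spec(0.1)
  expect_identical(unname(sp01$n_per_group[c("patient", "control")]),
                   c(7L, 6L))
  expect_identical(sp01$n_regions, 12L)

  for (s in c(0.07, 0.25, 0.5, 1)) {
    spc <- default_paper_like_spec(s)
    expect_lt(max(abs(rowSums(spc$base_transition) - 1)), 1e-12)
    for (S in spc$state_covs) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
      expect_lt(max(ev) / min(ev), 1e3)
    }
  }
})

test_that("simulated metadata is plausible and MoCA tracks the linked metric", {
  sp <- default_paper_like_spec(0.25, seed = 21)
  sim <- simulate_cohort(sp)
  m <- sim$cohort$meta
  expect_true(all(m$age >= 18 & m$age <= 80))
  expect_true(all(m$education >= 0))
  expect_true(all(m$moca >= 0 & m$moca <= 30))
  # linked metric: occupancy of state 3 correlates positively with MoCA
  fo3 <- vapply(sim$true_paths, function(p)
    fractional_occupancy(p, sp$n_states)[3], numeric(1))
  expect_gt(cor(fo3, m$moca, method = "spearman"), 0)
})

test_that("ground-truth sidecar files round-trip the true paths", {
  sim <- simulate_cohort(k3_spec(2, n_per_group = c(patient = 2,
                                                    control = 2),
                                 n_timepoints = 30))
  dir <- withr::local_tempdir()
  write_synthetic_cohort(sim, dir)
  raw <- read.table(file.path(dir, "true_paths.tsv"), sep = "\t")
  expect_identical(unname(as.matrix(raw[, -1])),
                   unname(do.call(rbind, sim$true_paths)))
  A1 <- as.matrix(read.table(
    file.path(dir, "true_transition_sub001.tsv"), sep = "\t"))
  expect_equal(unname(A1), unname(sim$true_transitions[[1L]]),
               tolerance = 1e-12)
})
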
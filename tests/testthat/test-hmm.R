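test_that("forward-backward and Viterbi agree with exhaustive enumeration", {
  set.seed(11)
  for (i in 1:20) {
    K <- sample(2:3, 1)
    Tn <- sample(3:8, 1)
    R <- sample(2:3, 1)
    model <- random_tiny_model(K, R)
    obs <- matrix(rnorm(Tn * R), Tn, R)
    fb <- log_forward_backward(model, obs)
    bf <- brute_force_hmm(model, obs)
    expect_equal(fb$log_evidence, bf$log_evidence, tolerance = 1e-8)
    expect_identical(viterbi(model, obs), unname(bf$map_path))
    expect_lt(max(abs(rowSums(fb$posterior) - 1)), 1e-10)
    expect_lt(max(abs(apply(fb$pairwise_posteriors, 1, sum) - 1)), 1e-10)
  }
})

test_that("a single-state model degenerates to the iid Gaussian likelihood", {
  set.seed(2)
  R <- 4; Tn <- 30
  mu <- rnorm(R)
  S <- crossprod(matrix(rnorm(R * R), R)) + diag(R)
  model <- hmm_model(matrix(mu, 1), list(S), matrix(1, 1, 1), 1)
  obs <- matrix(rnorm(Tn * R), Tn, R)
  fb <- log_forward_backward(model, obs)
  # independent oracle: per-timepoint density via explicit quadratic form
  Sinv <- solve(S)
  ld <- apply(obs, 1, function(x)
    -0.5 * (R * log(2 * pi) + determinant(S)$modulus +
              t(x - mu) %*% Sinv %*% (x - mu)))
  expect_equal(fb$log_evidence, sum(ld), tolerance = 1e-8)
  expect_true(all(fb$posterior == 1))
  expect_identical(viterbi(model, obs), rep(1L, Tn))
})

test_that("with equal emissions a sticky chain stays in its initial state", {
  K <- 2; R <- 2
  A <- matrix(c(.99, .01, .01, .99), 2, 2, byrow = TRUE)
  model <- hmm_model(matrix(0, K, R), rep(list(diag(R)), K), A, c(1, 0))
  obs <- matrix(rnorm(20 * R), 20, R)
  expect_identical(viterbi(model, obs), rep(1L, 20))
})

test_that("EM recovers the generating parameters of a separated K=3 cohort", {
  sim <- simulate_cohort(k3_spec(7))
  coh <- standardize_cohort(sim$cohort)
  fit <- fit_hmm(coh, 3, n_restarts = 3, seed = 1, max_iter = 200)

  # the winning restart's log-likelihood trace is non-decreasing
  tr <- fit$model$fit_meta$ll_trace
  expect_true(all(diff(tr) > -1e-8 * abs(tr[-length(tr)])))

  # truth in standardized units: per-state sample means under the true path
  obs <- do.call(rbind, lapply(coh$series, function(s) t(s$data)))
  tp <- unlist(sim$true_paths)
  true_means <- t(vapply(1:3, function(k)
    colMeans(obs[tp == k, , drop = FALSE]), numeric(ncol(obs))))
  perm <- match_states(true_means, fit$model)
  inv <- order(perm)
  expect_lt(max(abs(fit$model$transition[inv, inv] -
                      sim$spec$base_transition)), 0.05)
  rel_err <- max(abs(fit$model$means[inv, ] - true_means)) /
    max(abs(true_means))
  expect_lt(rel_err, 0.10)

  # decoded paths recover the simulated chain almost everywhere
  acc <- mean(unlist(Map(function(p, tp) mean(perm[p$decoded_path] == tp),
                         fit$paths, sim$true_paths)))
  expect_gt(acc, 0.95)

  # soft (posterior-mean) and hard occupancy agree on separated data
  for (p in fit$paths) {
    soft <- colMeans(p$posterior)
    hard <- fractional_occupancy(p$decoded_path, 3)
    expect_lt(max(abs(soft - hard)), 0.05)
  }
})

test_that("fitting is deterministic given the seed", {
  sim <- simulate_cohort(k3_spec(3, n_per_group = c(patient = 4,
                                                    control = 4)))
  coh <- standardize_cohort(sim$cohort)
  f1 <- fit_hmm(coh, 3, n_restarts = 2, seed = 42, max_iter = 60)
  f2 <- fit_hmm(coh, 3, n_restarts = 2, seed = 42, max_iter = 60)
  expect_identical(f1$model$means, f2$model$means)
  expect_identical(f1$model$transition, f2$model$transition)
  expect_identical(lapply(f1$paths, `[[`, "decoded_path"),
                   lapply(f2$paths, `[[`, "decoded_path"))
})

test_that("K = 1 EM equals the pooled maximum-likelihood Gaussian", {
  sim <- simulate_cohort(k3_spec(6, n_per_group = c(patient = 3,
                                                    control = 3),
                                 n_timepoints = 100))
  coh <- sim$cohort
  fit <- fit_hmm(coh, 1, n_restarts = 1, seed = 1, max_iter = 50)
  obs <- do.call(rbind, lapply(coh$series, function(s) t(s$data)))
  mle_mean <- colMeans(obs)
  xc <- sweep(obs, 2, mle_mean)
  mle_cov <- crossprod(xc) / nrow(obs)
  ridge <- 1e-6 * mean(diag(mle_cov))
  expect_equal(unname(fit$model$means[1, ]), unname(mle_mean),
               tolerance = 1e-8)
  expect_equal(unname(fit$model$covariances[[1]]),
               unname(mle_cov + diag(ridge, ncol(obs))),
               tolerance = 1e-6)
  expect_identical(fit$model$transition, matrix(1, 1, 1))
})

test_that("EM is equivariant under relabelling of the initialization", {
  sim <- simulate_cohort(k3_spec(5, n_per_group = c(patient = 3,
                                                    control = 3),
                                 n_timepoints = 120))
  coh <- standardize_cohort(sim$cohort)
  obs_list <- dynstates:::cohort_observations(coh)
  init <- dynstates:::init_model(obs_list, 3, seed = 99)
  fit_a <- dynstates:::em_run(obs_list, 3, init, tol = 1e-6,
                              max_iter = 40)
  perm <- c(3L, 1L, 2L)  # state k of init becomes state perm[k]
  init_p <- permute_states(init, perm)
  fit_b <- dynstates:::em_run(obs_list, 3, init_p, tol = 1e-6,
                              max_iter = 40)
  expect_equal(permute_states(fit_a, perm)$means, fit_b$means,
               tolerance = 1e-9)
  expect_equal(permute_states(fit_a, perm)$transition, fit_b$transition,
               tolerance = 1e-9)
  expect_equal(fit_a$log_likelihood, fit_b$log_likelihood,
               tolerance = 1e-9)
})

test_that("model serialization round-trips through JSON", {
  set.seed(31)
  model <- random_tiny_model(3, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_model(model, path)
  model2 <- read_hmm_model(path)
  expect_equal(model2$means, model$means, tolerance = 1e-12)
  expect_equal(model2$transition, model$transition, tolerance = 1e-12)
  expect_equal(model2$covariances[[2]], model$covariances[[2]],
               tolerance = 1e-12)
})

test_that("order selection recovers K and flags overfitted states", {
  sim <- simulate_cohort(k3_spec(11, jitter = 0.3))
  coh <- standardize_cohort(sim$cohort)
  sel <- select_model_order(coh, c(2, 3, 4), n_restarts = 2, seed = 1,
                            max_iter = 100)
  expect_identical(sel$chosen_K, 3L)
  expect_identical(sel$report$n_near_empty[sel$report$K == 3], 0L)
  expect_equal(sel$report$bic,
               -2 * sel$report$log_likelihood +
                 sel$report$n_params * log(20 * 220))
  expect_equal(sel$report$n_params,
               (sel$report$K - 1) + sel$report$K * (sel$report$K - 1) +
                 sel$report$K * 8 + sel$report$K * 8 * 9 / 2)
})

test_that("order selection with a single candidate returns it", {
  sim <- simulate_cohort(k3_spec(13, n_per_group = c(patient = 3,
                                                     control = 3),
                                 n_timepoints = 80))
  sel <- select_model_order(standardize_cohort(sim$cohort), 2,
                            n_restarts = 1, seed = 1, max_iter = 40)
  expect_identical(sel$chosen_K, 2L)
})
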
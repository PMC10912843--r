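# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no data files.

# Well-separated K = 3 ground truth used by recovery and selection tests.
# `jitter` adds between-subject transition heterogeneity; recovery tests
# use 0 (clean parameters), selection tests a realistic positive value.
k3_spec <- function(seed, jitter = 0, n_per_group = c(patient = 10,
                                                      control = 10),
                    n_timepoints = 220) {
  K <- 3; R <- 8
  A <- matrix(0.05, K, K); diag(A) <- 0.9
  means <- matrix(0, K, R)
  means[1, 1:3] <- 1.5
  means[2, 4:6] <- 1.5
  means[3, c(7, 8, 1)] <- -1.5
  ground_truth_spec(K, R, n_timepoints, 2, A, rep(1 / 3, 3), means,
                    rep(list(diag(R)), K),
                    n_per_group = n_per_group,
                    subject_jitter_sd = jitter, seed = seed)
}

# Random small HMM for oracle comparisons.
random_tiny_model <- function(K, R) {
  A <- matrix(stats::runif(K * K), K)
  A <- A / rowSums(A)
  pi0 <- stats::runif(K); pi0 <- pi0 / sum(pi0)
  means <- matrix(stats::rnorm(K * R, sd = 2), K, R)
  covs <- lapply(seq_len(K), function(k) {
    M <- matrix(stats::rnorm(R * R), R)
    crossprod(M) + diag(R) * 0.5
  })
  hmm_model(means, covs, A, pi0)
}

# Exhaustive-enumeration oracle: log-evidence by summing over all K^T
# paths, and the exact MAP path. Independent of the forward-backward code.
brute_force_hmm <- function(model, obs) {
  K <- model$n_states; Tn <- nrow(obs); R <- ncol(obs)
  ld <- sapply(seq_len(K), function(k) {
    U <- chol(model$covariances[[k]])
    z <- backsolve(U, t(obs) - model$means[k, ], transpose = TRUE)
    -0.5 * (R * log(2 * pi) + 2 * sum(log(diag(U))) + colSums(z * z))
  })
  ld <- matrix(ld, nrow = Tn)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- apply(paths, 1L, function(p) {
    v <- log(model$initial_dist[p[1L]]) + ld[1L, p[1L]]
    if (Tn > 1L)
      for (t in 2:Tn)
        v <- v + log(model$transition[p[t - 1L], p[t]]) + ld[t, p[t]]
    v
  })
  m <- max(lp)
  list(log_evidence = m + log(sum(exp(lp - m))),
       map_path = paths[which.max(lp), ])
}

# Brute-force optimal assignment over all permutations (small n).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1L, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  costs <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(n), p)]))
  perms[which.min(costs), ]
}

# Minimal subject_dynamics stand-ins for statistics tests: a K x n matrix
# of per-state values becomes a list of n subjects.
mock_dynamics <- function(values, switching = NULL) {
  values <- as.matrix(values)
  lapply(seq_len(ncol(values)), function(i) {
    structure(list(subject_id = sprintf("m%03d", i),
                   fractional_occupancy = values[, i],
                   mean_lifetime = values[, i],
                   mean_interval = values[, i],
                   switching_rate = if (is.null(switching)) values[1L, i]
                                    else switching[[i]]),
              class = "subject_dynamics")
  })
}
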
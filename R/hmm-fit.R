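#' Gaussian-emission hidden Markov model
#'
#' Container for a fitted (or hand-built) K-state HMM whose emission in
#' state k is multivariate normal with mean `means[k, ]` (first-order
#' statistic: mean activity) and covariance `covariances[[k]]`
#' (second-order statistic). Hidden dynamics are a first-order Markov
#' chain with row-stochastic `transition` and initial distribution
#' `initial_dist`.
#'
#' @param means K x n_regions matrix of state means.
#' @param covariances list of K SPD covariance matrices.
#' @param transition K x K row-stochastic matrix.
#' @param initial_dist length-K probability vector.
#' @param log_likelihood total log-likelihood of the training data (NA for
#'   hand-built models).
#' @param fit_meta list of fitting metadata (seed, restarts, iterations,
#'   converged, ll_trace).
#' @param region_labels optional region names for the observation axis.
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(means, covariances, transition, initial_dist,
                      log_likelihood = NA_real_, fit_meta = list(),
                      region_labels = NULL) {
  means <- as.matrix(means)
  K <- nrow(means); R <- ncol(means)
  if (length(covariances) != K) stop("need one covariance per state")
  for (k in seq_len(K))
    if (!is_spd(covariances[[k]], tol = 1e-8) ||
        nrow(covariances[[k]]) != R)
      stop("covariance of state ", k, " is not SPD n_regions x n_regions")
  check_row_stochastic(transition, 1e-10)
  if (nrow(transition) != K) stop("transition must be K x K")
  if (length(initial_dist) != K || any(initial_dist < 0) ||
      abs(sum(initial_dist) - 1) > 1e-10)
    stop("initial_dist must be a length-K probability vector")
  structure(
    list(n_states = K, n_regions = R, means = means,
         covariances = covariances, transition = transition,
         initial_dist = as.numeric(initial_dist),
         log_likelihood = log_likelihood,
         n_params = hmm_n_params(K, R),
         fit_meta = fit_meta,
         region_labels = region_labels),
    class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model> K =", x$n_states, "states,", x$n_regions, "regions",
      "; logLik =", format(x$log_likelihood), "\n")
  invisible(x)
}

# Free parameters of a K-state Gaussian HMM in R dimensions:
# initial dist (K-1), transition (K(K-1)), means (KR), covariances
# (K R(R+1)/2).
#' @keywords internal
hmm_n_params <- function(K, R) {
  (K - 1) + K * (K - 1) + K * R + K * R * (R + 1) / 2
}

# Per-timepoint Gaussian log-densities, T x K, Cholesky-based.
#' @keywords internal
gaussian_logdens <- function(obs, model) {
  K <- model$n_states; R <- model$n_regions
  out <- matrix(0, nrow(obs), K)
  for (k in seq_len(K)) {
    U <- chol(model$covariances[[k]])
    z <- backsolve(U, t(obs) - model$means[k, ], transpose = TRUE)
    out[, k] <- -0.5 * (R * log(2 * pi) + 2 * sum(log(diag(U))) +
                          colSums(z * z))
  }
  out
}

#' Log-space forward-backward recursion for one sequence
#'
#' Computes the evidence `log p(observations | model)`, per-timepoint state
#' posteriors (gamma) and pairwise transition posteriors (xi) for a single
#' subject's sequence. All recursions run on log-probabilities with
#' log-sum-exp rescaling, so sequences of hundreds of timepoints in a
#' hundred dimensions are numerically stable.
#'
#' @param model an [hmm_model()].
#' @param observations T x n_regions numeric matrix (timepoints in rows).
#' @return list with `log_evidence` (scalar), `posterior` (T x K, rows sum
#'   to 1) and `pairwise_posteriors` ((T-1) x K x K array; each `[t, , ]`
#'   slice sums to 1).
#' @export
log_forward_backward <- function(model, observations) {
  observations <- as.matrix(observations)
  if (any(!is.finite(observations))) stop("non-finite observations")
  if (ncol(observations) != model$n_regions)
    stop("observations have ", ncol(observations),
         " columns; model expects ", model$n_regions)
  ldens <- gaussian_logdens(observations, model)
  fb_from_ldens(model, ldens, want_xi = TRUE)
}

# Core recursion given precomputed log-densities; want_xi = FALSE skips the
# pairwise array (EM accumulates the summed xi instead).
#' @keywords internal
fb_from_ldens <- function(model, ldens, want_xi = FALSE) {
  Tn <- nrow(ldens); K <- ncol(ldens)
  A <- model$transition
  la <- matrix(-Inf, Tn, K)
  lb <- matrix(0, Tn, K)
  la[1L, ] <- log(model$initial_dist) + ldens[1L, ]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      m <- max(la[t - 1L, ])
      la[t, ] <- ldens[t, ] + m + log(exp(la[t - 1L, ] - m) %*% A)
    }
    for (t in (Tn - 1L):1L) {
      v <- ldens[t + 1L, ] + lb[t + 1L, ]
      m <- max(v)
      lb[t, ] <- m + log(A %*% exp(v - m))
    }
  }
  log_evidence <- log_sum_exp(la[Tn, ])
  lg <- la + lb - log_evidence
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  xi <- NULL
  if (Tn > 1L) {
    lA <- log(A)
    if (want_xi) xi <- array(0, c(Tn - 1L, K, K))
    for (t in seq_len(Tn - 1L)) {
      lx <- outer(la[t, ], ldens[t + 1L, ] + lb[t + 1L, ], `+`) + lA -
        log_evidence
      x <- exp(lx)
      x <- x / sum(x)
      xi_sum <- xi_sum + x
      if (want_xi) xi[t, , ] <- x
    }
  }
  list(log_evidence = log_evidence, posterior = gamma,
       pairwise_posteriors = xi, xi_sum = xi_sum)
}

#' Most probable joint state path (Viterbi decoding)
#'
#' Dynamic-programming maximisation of the joint path posterior. Ties are
#' broken toward the lower state index.
#'
#' @inheritParams log_forward_backward
#' @return integer vector of length T with states in 1..K.
#' @export
viterbi <- function(model, observations) {
  observations <- as.matrix(observations)
  ldens <- gaussian_logdens(observations, model)
  Tn <- nrow(ldens); K <- model$n_states
  lA <- log(model$transition)
  delta <- log(model$initial_dist) + ldens[1L, ]
  back <- matrix(0L, Tn, K)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      cand <- delta + lA  # K x K: cand[i, j] = delta_i + log A_ij
      back[t, ] <- apply(cand, 2L, which.max)  # first max = lowest index
      delta <- cand[cbind(back[t, ], seq_len(K))] + ldens[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1L)
    for (t in (Tn - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  path
}

# Observation matrices (T x R) per subject from a cohort.
#' @keywords internal
cohort_observations <- function(x) lapply(x$series, function(s) t(s$data))

# One EM run from a given initialization; obs_list is a list of T x R
# matrices. Returns model + trace. Starved states (total responsibility
# below n_regions + 1) are re-seeded once per event from the worst-fit
# timepoints; the covariance ridge keeps M-steps well-posed.
#' @keywords internal
em_run <- function(obs_list, K, init, tol, max_iter) {
  R <- ncol(obs_list[[1L]])
  model <- init
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  starved_events <- 0L
  reseed_count <- integer(K)  # per-state cap: thrashing helps nobody
  for (iter in seq_len(max_iter)) {
    # E step
    ll <- 0
    g1 <- numeric(K)
    xi_tot <- matrix(0, K, K)
    occ <- numeric(K)
    sum_x <- matrix(0, K, R)
    scat <- vector("list", K)
    for (k in seq_len(K)) scat[[k]] <- matrix(0, R, R)
    gammas <- vector("list", length(obs_list))
    for (s in seq_along(obs_list)) {
      obs <- obs_list[[s]]
      ldens <- gaussian_logdens(obs, model)
      fb <- fb_from_ldens(model, ldens)
      ll <- ll + fb$log_evidence
      g <- fb$posterior
      gammas[[s]] <- g
      g1 <- g1 + g[1L, ]
      xi_tot <- xi_tot + fb$xi_sum
      occ <- occ + colSums(g)
      sum_x <- sum_x + t(g) %*% obs
    }
    ll_trace <- c(ll_trace, ll)

    # starvation check before the M step
    starved <- which(occ < R + 1 & reseed_count < 2L)
    if (length(starved)) {
      model <- reseed_states(model, obs_list, starved)
      reseed_count[starved] <- reseed_count[starved] + 1L
      starved_events <- starved_events + length(starved)
      message("re-seeded starved state(s) ",
              paste(starved, collapse = ", "), " at iteration ", iter)
      next
    }
    # states past the reseed cap fall back to a floored covariance M step
    occ <- pmax(occ, R + 1)

    # M step
    means <- sum_x / occ
    for (s in seq_along(obs_list)) {
      obs <- obs_list[[s]]
      g <- gammas[[s]]
      for (k in seq_len(K)) {
        xc <- obs - matrix(means[k, ], nrow(obs), R, byrow = TRUE)
        scat[[k]] <- scat[[k]] + crossprod(xc * g[, k], xc)
      }
    }
    covs <- vector("list", K)
    for (k in seq_len(K)) {
      S <- scat[[k]] / occ[k]
      S <- (S + t(S)) / 2
      ridge <- 1e-6 * mean(diag(S))
      covs[[k]] <- S + diag(max(ridge, 1e-10), R)
    }
    A <- xi_tot / rowSums(xi_tot)
    pi0 <- g1 / sum(g1)
    model <- hmm_model(means, covs, A, pi0, log_likelihood = ll)

    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  model$log_likelihood <- ll_trace[length(ll_trace)]
  model$fit_meta <- list(iterations = length(ll_trace),
                         converged = converged, ll_trace = ll_trace,
                         starved_events = starved_events)
  model
}

# Split-merge rescue: EM with many states regularly converges with two
# states sharing one emission distribution (duplicate means, modelling
# dwell-time heterogeneity) while a small genuine cluster goes unmodelled
# and shows up as a block of badly fit timepoints. The move reseeds one
# state of the closest pair at the centroid of the worst-fit timepoints;
# the caller re-runs EM and keeps the result only if the log-likelihood
# improves. Deterministic.
# Two failure modes coexist in high-K EM solutions: a duplicated state
# pair (near-identical means, modelling between-subject dwell
# heterogeneity) and a genuine small cluster absorbed into a neighbouring
# state's widened covariance. The move frees one state of the closest
# mean pair and re-seeds it on the minor mode of the most bimodal state
# (largest within-state 2-means gain); the caller re-runs EM and keeps
# the result only if the log-likelihood improves. Deterministic.
#' @keywords internal
rescue_duplicate_state <- function(model, obs_list, seed = 0L) {
  all_obs <- do.call(rbind, obs_list)
  R <- ncol(all_obs)
  ld <- gaussian_logdens(all_obs, model)
  assign <- max.col(ld, ties.method = "first")
  D <- as.matrix(stats::dist(model$means))
  diag(D) <- Inf
  j <- which(D == min(D), arr.ind = TRUE)[1L, 2L]

  best_gain <- -Inf
  best_members <- NULL
  for (k in seq_len(model$n_states)) {
    if (k == j) next
    pts <- all_obs[assign == k, , drop = FALSE]
    if (nrow(pts) < 4L * (R + 1L)) next
    km <- suppressWarnings(  # a non-converged 2-means screen is fine
      with_seed(seed, stats::kmeans(pts, centers = 2L, iter.max = 30L,
                                    algorithm = "Lloyd")))
    wss1 <- sum(scale(pts, scale = FALSE)^2)
    gain <- (wss1 - sum(km$withinss)) / nrow(pts)
    minor <- which.min(tabulate(km$cluster, 2L))
    members <- pts[km$cluster == minor, , drop = FALSE]
    if (gain > best_gain && nrow(members) > R + 1L) {
      best_gain <- gain
      best_members <- members
    }
  }
  if (is.null(best_members)) return(model)
  model$means[j, ] <- colMeans(best_members)
  S <- stats::cov(best_members)
  model$covariances[[j]] <- S + diag(0.5 * mean(diag(S)) + 1e-6, R)
  model
}

# Move starved states onto the currently worst-fit timepoints and reset
# their covariance to the pooled covariance.
#' @keywords internal
reseed_states <- function(model, obs_list, starved) {
  all_obs <- do.call(rbind, obs_list)
  ld <- gaussian_logdens(all_obs, model)
  worst <- order(apply(ld, 1L, max))[seq_along(starved)]
  pooled <- stats::cov(all_obs) + diag(1e-6, ncol(all_obs))
  for (j in seq_along(starved)) {
    k <- starved[[j]]
    model$means[k, ] <- all_obs[worst[[j]], ]
    model$covariances[[k]] <- pooled
  }
  model
}

# k-means++ seeding: the first centre is uniform, later centres are drawn
# with probability proportional to squared distance from the nearest
# chosen centre, so small but well-separated clusters are found even when
# plain k-means would rather split a dominant cluster.
#' @keywords internal
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (k in seq_len(K)[-1L]) {
    centers[k, ] <- X[sample.int(n, 1L, prob = d2), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ])^2))
  }
  centers
}

# k-means / pooled-covariance / sticky-transition init. Two styles are
# alternated across restarts for basin diversity: "pp" seeds k-means with
# k-means++ (finds small well-separated clusters that plain k-means would
# rather ignore) and uses the tighter within-cluster covariance; "plain"
# uses stock k-means and the total covariance (broader responsibilities,
# which reach the subject-specialised optima of heterogeneous cohorts).
#' @keywords internal
init_model <- function(obs_list, K, seed, style = c("pp", "plain")) {
  style <- match.arg(style)
  all_obs <- do.call(rbind, obs_list)
  R <- ncol(all_obs)
  km <- with_seed(seed, {
    if (K == 1L) NULL
    else if (style == "pp")
      stats::kmeans(all_obs, centers = kmeanspp_centers(all_obs, K),
                    iter.max = 100L, algorithm = "Lloyd")
    else suppressWarnings(
      stats::kmeans(all_obs, centers = K, nstart = 1L, iter.max = 50L))
  })
  centers <- if (K == 1L) matrix(colMeans(all_obs), 1L, R) else km$centers
  centers <- centers[order(centers[, 1L]), , drop = FALSE]  # stable order
  pooled <- if (K == 1L || style == "plain") stats::cov(all_obs)
            else stats::cov(all_obs - km$centers[km$cluster, , drop = FALSE])
  pooled <- pooled + diag(1e-6, R)
  A <- matrix(0.2 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1L) 0.8 else 1
  hmm_model(centers, rep(list(pooled), K), A, rep(1 / K, K))
}

#' Fit a group-level Gaussian HMM to a cohort by EM (Baum-Welch)
#'
#' One model is fitted jointly to all subjects' sequences (each subject is
#' an independent realisation sharing states and transition matrix), then
#' each subject's state path is decoded. Multiple random restarts guard
#' against local optima; the restart with the highest final log-likelihood
#' wins. The fit is deterministic given `seed`.
#'
#' @param x a [cohort()] (series should be standardized; see
#'   [standardize_cohort()]).
#' @param K number of states.
#' @param n_restarts number of k-means-seeded EM restarts.
#' @param seed integer seed controlling all restarts.
#' @param tol relative log-likelihood improvement below which EM stops.
#' @param max_iter maximum EM iterations per restart.
#' @param decoder `"gamma"` (argmax of the marginal posterior; default) or
#'   `"viterbi"` (joint MAP path) for the `decoded_path` of each subject.
#' @param n_rescues maximum number of split-merge refinement attempts on
#'   the winning restart: the closest pair of state means is treated as a
#'   duplicate, one of the pair is reseeded at the centroid of the
#'   worst-fit timepoints, and EM is re-run; the move is kept only when
#'   it improves the log-likelihood. Guards against the common local
#'   optimum in which two states share one emission distribution while a
#'   small genuine cluster goes unmodelled.
#' @return list with `model` (an [hmm_model()]) and `paths` (named list of
#'   `state_path` objects with fields `subject_id`, `decoded_path`,
#'   `viterbi_path`, `posterior`).
#' @export
fit_hmm <- function(x, K, n_restarts = 10L, seed = 1L, tol = 1e-6,
                    max_iter = 500L, decoder = c("gamma", "viterbi"),
                    n_rescues = 2L) {
  stopifnot(inherits(x, "cohort"), K >= 1L)
  decoder <- match.arg(decoder)
  obs_list <- cohort_observations(x)
  total_T <- sum(vapply(obs_list, nrow, integer(1)))
  R <- ncol(obs_list[[1L]])
  if (total_T <= hmm_n_params(K, R))
    warning("total timepoints (", total_T, ") do not exceed parameter ",
            "count (", hmm_n_params(K, R), "); fit may be degenerate")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- init_model(obs_list, K, subject_seed(seed, r),
                       style = if (r %% 2L == 1L) "pp" else "plain")
    fit <- em_run(obs_list, K, init, tol, max_iter)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood)
      best <- fit
  }
  # likelihood-guided split-merge refinement of the winning restart
  rescues <- 0L
  if (K > 1L) {
    for (a in seq_len(n_rescues)) {
      cand_init <- rescue_duplicate_state(best, obs_list)
      cand <- em_run(obs_list, K, cand_init, tol, max_iter)
      if (cand$log_likelihood > best$log_likelihood) {
        best <- cand
        rescues <- rescues + 1L
      } else break
    }
  }
  best$fit_meta$rescues <- rescues
  best$fit_meta$seed <- seed
  best$fit_meta$restarts <- n_restarts
  best$region_labels <- x$series[[1L]]$region_labels
  paths <- lapply(seq_along(obs_list), function(s) {
    obs <- obs_list[[s]]
    fb <- log_forward_backward(best, obs)
    vit <- viterbi(best, obs)
    dec <- apply(fb$posterior, 1L, which.max)
    structure(list(subject_id = names(obs_list)[[s]],
                   decoded_path = if (decoder == "gamma") dec else vit,
                   gamma_path = dec,
                   viterbi_path = vit,
                   posterior = fb$posterior,
                   log_evidence = fb$log_evidence),
              class = "state_path")
  })
  names(paths) <- names(obs_list)
  list(model = best, paths = paths)
}

#' Serialize / load an HMM model as JSON
#'
#' @param model an [hmm_model()].
#' @param path file path.
#' @return `write_hmm_model` returns `path` invisibly; `read_hmm_model`
#'   returns the reconstructed [hmm_model()].
#' @export
write_hmm_model <- function(model, path) {
  stopifnot(inherits(model, "hmm_model"))
  obj <- list(n_states = model$n_states, n_regions = model$n_regions,
              means = model$means, covariances = model$covariances,
              transition = model$transition,
              initial_dist = model$initial_dist,
              log_likelihood = model$log_likelihood,
              fit_meta = model$fit_meta[setdiff(names(model$fit_meta),
                                                "ll_trace")],
              region_labels = model$region_labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- obj$covariances
  if (is.array(covs) && length(dim(covs)) == 3L)
    covs <- lapply(seq_len(dim(covs)[1L]), function(k) covs[k, , ])
  hmm_model(obj$means, covs, obj$transition, obj$initial_dist,
            log_likelihood = obj$log_likelihood,
            fit_meta = as.list(obj$fit_meta),
            region_labels = obj$region_labels)
}

#' Write decoded state paths as a per-subject TSV
#'
#' Columns: timepoint, decoded_state, viterbi_state, then K posterior
#' columns `p_state1..p_stateK`.
#'
#' @param paths list of `state_path` objects from [fit_hmm()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_state_paths <- function(paths, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in paths) {
    K <- ncol(p$posterior)
    df <- data.frame(timepoint = seq_along(p$decoded_path),
                     decoded_state = p$decoded_path,
                     viterbi_state = p$viterbi_path)
    post <- as.data.frame(p$posterior)
    names(post) <- sprintf("p_state%d", seq_len(K))
    utils::write.table(cbind(df, post),
                       file.path(dir, paste0(p$subject_id, "_path.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
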
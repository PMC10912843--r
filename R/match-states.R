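# Optimal assignment (Hungarian problem) via Jonker-Volgenant shortest
# augmenting paths. cost is an n x n matrix; returns for each row the
# assigned column, minimizing total cost. O(n^3); exact.
#' @keywords internal
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(is.matrix(cost), ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1L)  # row potentials (1-based with dummy at n+1)
  v <- numeric(n + 1L)  # column potentials
  p <- integer(n + 1L)  # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j]] <- j
  assign
}

#' Match the states of two HMMs by mean-vector proximity
#'
#' HMM state labels are arbitrary: two fits of the same data (or a fit and
#' the generating ground truth) may use permuted labels. This finds the
#' permutation minimizing the total Euclidean distance between matched
#' state mean vectors, by optimal assignment.
#'
#' @param reference,other [hmm_model()] objects with equal K and
#'   n_regions; `other` may also be a plain K x n_regions mean matrix.
#' @return integer permutation `perm` of 1..K such that state k of `other`
#'   corresponds to state `perm[k]` of `reference`.
#' @examples
#' m <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
#' covs <- list(diag(2), diag(2))
#' a <- hmm_model(m, covs, diag(2), c(.5, .5))
#' b <- hmm_model(m[2:1, ], covs, diag(2), c(.5, .5))
#' match_states(a, b)  # 2 1
#' @export
match_states <- function(reference, other) {
  ref_means <- if (inherits(reference, "hmm_model")) reference$means
               else as.matrix(reference)
  oth_means <- if (inherits(other, "hmm_model")) other$means
               else as.matrix(other)
  if (!all(dim(ref_means) == dim(oth_means)))
    stop("models differ in K or n_regions: ",
         paste(dim(ref_means), collapse = "x"), " vs ",
         paste(dim(oth_means), collapse = "x"))
  K <- nrow(ref_means)
  cost <- matrix(0, K, K)
  for (i in seq_len(K))
    for (j in seq_len(K))
      cost[i, j] <- sqrt(sum((oth_means[i, ] - ref_means[j, ])^2))
  solve_assignment(cost)
}

#' Relabel an HMM's states by a permutation
#'
#' @param model an [hmm_model()].
#' @param perm integer permutation as returned by [match_states()]: state k
#'   of `model` becomes state `perm[k]` of the result.
#' @return The relabelled [hmm_model()].
#' @export
permute_states <- function(model, perm) {
  stopifnot(inherits(model, "hmm_model"),
            sort(perm) == seq_len(model$n_states))
  inv <- order(perm)
  hmm_model(model$means[inv, , drop = FALSE],
            model$covariances[inv],
            model$transition[inv, inv, drop = FALSE],
            model$initial_dist[inv],
            log_likelihood = model$log_likelihood,
            fit_meta = model$fit_meta,
            region_labels = model$region_labels)
}
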
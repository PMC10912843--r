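#' Select the number of HMM states
#'
#' Fits the model for each candidate K and scores it by BIC together with a
#' state-occupancy degeneracy check. BIC is
#' `-2 logL + n_params * log(total timepoints)` with
#' `n_params = (K-1) + K(K-1) + K R + K R(R+1)/2`; it plays the role the
#' variational free energy plays in Bayesian HMM toolboxes (both penalize
#' complexity against fit). A state is *near-empty* at a given K when its
#' median fractional occupancy across subjects falls below `1/(10 K)`;
#' such states signal an over-specified model even when BIC is flat.
#'
#' The chosen K is the smallest candidate whose BIC lies within one
#' BIC standard error of the minimum (the SE is estimated from the
#' between-subject spread of per-subject deviance contributions) *and*
#' that has zero near-empty states. If no candidate satisfies the
#' occupancy condition the BIC minimum is returned. The full per-K report
#' is always returned so users can override the choice.
#'
#' @param x a [cohort()].
#' @param candidate_Ks integer vector of candidate state counts.
#' @param n_restarts,seed,tol,max_iter passed to [fit_hmm()].
#' @return An object of class `order_selection`: data.frame `report` with
#'   columns K, log_likelihood, n_params, bic, bic_se, median_fo,
#'   n_near_empty; plus `chosen_K` and the fitted models in `fits`.
#' @export
select_model_order <- function(x, candidate_Ks, n_restarts = 3L, seed = 1L,
                               tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(x, "cohort"), length(candidate_Ks) >= 1L)
  candidate_Ks <- sort(unique(as.integer(candidate_Ks)))
  tr <- x$series[[1L]]$tr_seconds
  total_T <- sum(vapply(x$series, function(s) ncol(s$data), integer(1)))
  rows <- vector("list", length(candidate_Ks))
  fits <- vector("list", length(candidate_Ks))
  for (i in seq_along(candidate_Ks)) {
    K <- candidate_Ks[[i]]
    fit <- fit_hmm(x, K, n_restarts = n_restarts, seed = seed, tol = tol,
                   max_iter = max_iter)
    fits[[i]] <- fit
    fo <- vapply(fit$paths, function(p)
      fractional_occupancy(p$decoded_path, K), numeric(K))
    fo <- matrix(fo, nrow = K)  # K x n_subjects
    med_fo_state <- apply(fo, 1L, stats::median)
    n_near_empty <- sum(med_fo_state < 1 / (10 * K))
    dev_s <- -2 * vapply(fit$paths, `[[`, numeric(1), "log_evidence")
    bic_se <- stats::sd(dev_s) * sqrt(length(dev_s))
    rows[[i]] <- data.frame(
      K = K,
      log_likelihood = fit$model$log_likelihood,
      n_params = fit$model$n_params,
      bic = -2 * fit$model$log_likelihood +
        fit$model$n_params * log(total_T),
      bic_se = bic_se,
      median_fo = stats::median(fo),
      n_near_empty = n_near_empty)
  }
  report <- do.call(rbind, rows)
  best <- which.min(report$bic)
  cutoff <- report$bic[best] + report$bic_se[best]
  ok <- report$bic <= cutoff & report$n_near_empty == 0L
  chosen_K <- if (any(ok)) report$K[which(ok)[1L]] else report$K[best]
  names(fits) <- paste0("K", report$K)
  structure(list(report = report, chosen_K = chosen_K, fits = fits,
                 tr_seconds = tr),
            class = "order_selection")
}

#' @export
print.order_selection <- function(x, ...) {
  print(x$report, row.names = FALSE)
  cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}
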
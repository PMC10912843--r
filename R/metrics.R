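#' Segment a state path into visits (run-length encoding)
#'
#' A *visit* is a maximal run of consecutive timepoints in the same state.
#' Visits tile the path with no gaps; consecutive visits differ in state.
#'
#' @param path integer state sequence.
#' @return data.frame with columns `state`, `start`, `end` (0-based
#'   inclusive indices) and `length` (in timepoints).
#' @examples
#' run_length_encode(c(1, 1, 2, 2, 2, 1))
#' @export
run_length_encode <- function(path) {
  stopifnot(length(path) >= 1L, all(is.finite(path)), all(path >= 1))
  r <- rle(as.integer(path))
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start = ends - r$lengths,
             end = ends - 1L,
             length = r$lengths)
}

#' Fractional occupancy of each state
#'
#' Proportion of timepoints spent in each state; sums to 1.
#'
#' @param path integer state sequence.
#' @param K number of states.
#' @return length-K numeric vector.
#' @examples
#' fractional_occupancy(c(1, 1, 2, 2, 2, 1, 3, 3, 1, 1), K = 3)
#' @export
fractional_occupancy <- function(path, K) {
  stopifnot(length(path) >= 1L, all(path >= 1), all(path <= K))
  tabulate(as.integer(path), nbins = K) / length(path)
}

#' Mean lifetime (dwell time) of each state, in seconds
#'
#' Mean duration of the visits to each state. A visit spanning samples
#' `start..end` lasts `(end - start + 1) * tr_seconds`: every sample
#' occupied contributes one TR of dwell time. States never visited give
#' NaN.
#'
#' @param visits data.frame from [run_length_encode()].
#' @param K number of states.
#' @param tr_seconds sampling interval in seconds.
#' @return length-K numeric vector (seconds).
#' @export
state_lifetimes <- function(visits, K, tr_seconds) {
  out <- rep(NaN, K)
  for (k in seq_len(K)) {
    len <- visits$length[visits$state == k]
    if (length(len)) out[k] <- mean(len) * tr_seconds
  }
  out
}

#' Mean interval time between consecutive visits to each state, in seconds
#'
#' For each state, the gaps are the numbers of timepoints strictly between
#' the end of one visit and the start of the next visit to that state;
#' the mean gap times TR is the interval time. Time before the first visit
#' and after the last is censored, not an interval, so states visited at
#' most once give NaN.
#'
#' @inheritParams state_lifetimes
#' @return length-K numeric vector (seconds).
#' @export
state_intervals <- function(visits, K, tr_seconds) {
  out <- rep(NaN, K)
  for (k in seq_len(K)) {
    v <- visits[visits$state == k, , drop = FALSE]
    if (nrow(v) >= 2L) {
      gaps <- v$start[-1L] - v$end[-nrow(v)] - 1L
      out[k] <- mean(gaps) * tr_seconds
    }
  }
  out
}

#' Switching rate of a state path, in Hz
#'
#' Number of state changes between adjacent timepoints divided by the time
#' the adjacent pairs span, `(T - 1) * tr_seconds`.
#'
#' @param path integer state sequence of length >= 2.
#' @param tr_seconds sampling interval in seconds.
#' @return scalar rate in Hz.
#' @examples
#' switching_rate(c(1, 1, 2, 2, 2, 1, 3, 3, 1, 1), tr_seconds = 2)
#' @export
switching_rate <- function(path, tr_seconds) {
  Tn <- length(path)
  stopifnot(Tn >= 2L)
  sum(path[-1L] != path[-Tn]) / ((Tn - 1) * tr_seconds)
}

# Per-state switching rate: switches out of state k per second spent in k
# (optional companion to the scalar rate).
#' @keywords internal
per_state_switching_rate <- function(path, K, tr_seconds) {
  Tn <- length(path)
  out <- rep(NaN, K)
  from <- path[-Tn]; to <- path[-1L]
  for (k in seq_len(K)) {
    tk <- sum(from == k)
    if (tk > 0) out[k] <- sum(from == k & to != k) / (tk * tr_seconds)
  }
  out
}

#' Empirical transition matrix of one subject's state path
#'
#' Counts adjacent state pairs (self-transitions included) and row-
#' normalizes. Rows of states never departed from (zero counts) are NaN.
#' An off-diagonal view (diagonal zeroed, rows renormalized) is also
#' returned for analyses of between-state switching only.
#'
#' @param path integer state sequence of length >= 2.
#' @param K number of states.
#' @return list with `counts` (K x K integer), `probs` (K x K, rows sum to
#'   1 where defined) and `probs_offdiag` (diagonal excluded view).
#' @examples
#' subject_transition_matrix(c(1, 1, 2, 2, 2, 1, 3, 3, 1, 1), K = 3)$counts
#' @export
subject_transition_matrix <- function(path, K) {
  Tn <- length(path)
  stopifnot(Tn >= 2L, all(path >= 1), all(path <= K))
  counts <- matrix(0L, K, K)
  idx <- cbind(path[-Tn], path[-1L])
  for (r in seq_len(nrow(idx)))
    counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
  rs <- rowSums(counts)
  probs <- counts / rs
  probs[rs == 0L, ] <- NaN
  off <- counts
  diag(off) <- 0L
  ro <- rowSums(off)
  probs_off <- off / ro
  probs_off[ro == 0L, ] <- NaN
  list(counts = counts, probs = probs, probs_offdiag = probs_off)
}

#' All temporal-dynamics metrics for one subject
#'
#' Computes the five per-subject properties from a decoded state path:
#' fractional occupancy, mean lifetime, mean interval time, switching rate
#' and the transition matrix, plus the per-state switching-rate variant
#' and soft (posterior-weighted) occupancy when a posterior is supplied.
#'
#' @param path integer state sequence (or a `state_path` from
#'   [fit_hmm()], in which case its `decoded_path` and posterior are
#'   used).
#' @param K number of states.
#' @param tr_seconds sampling interval in seconds.
#' @param subject_id identifier copied into the result.
#' @param posterior optional T x K posterior for soft occupancy.
#' @return An object of class `subject_dynamics`.
#' @export
subject_dynamics <- function(path, K, tr_seconds, subject_id = "subject",
                             posterior = NULL) {
  if (inherits(path, "state_path")) {
    posterior <- path$posterior
    subject_id <- path$subject_id
    path <- path$decoded_path
  }
  visits <- run_length_encode(path)
  tm <- subject_transition_matrix(path, K)
  structure(
    list(subject_id = subject_id,
         n_timepoints = length(path),
         tr_seconds = tr_seconds,
         fractional_occupancy = fractional_occupancy(path, K),
         soft_occupancy = if (!is.null(posterior)) colMeans(posterior),
         mean_lifetime = state_lifetimes(visits, K, tr_seconds),
         mean_interval = state_intervals(visits, K, tr_seconds),
         switching_rate = switching_rate(path, tr_seconds),
         switching_rate_per_state =
           per_state_switching_rate(path, K, tr_seconds),
         transition_counts = tm$counts,
         transition_probs = tm$probs,
         transition_probs_offdiag = tm$probs_offdiag,
         visits = visits),
    class = "subject_dynamics")
}

#' @export
print.subject_dynamics <- function(x, ...) {
  cat("<subject_dynamics>", x$subject_id, "- FO:",
      paste(format(x$fractional_occupancy, digits = 3), collapse = " "),
      "; switching", format(x$switching_rate, digits = 3), "Hz\n")
  invisible(x)
}

#' Dynamics for every subject of a decoded cohort
#'
#' @param paths named list of `state_path` objects (from [fit_hmm()]) or
#'   plain integer paths.
#' @param K number of states.
#' @param tr_seconds sampling interval in seconds.
#' @return named list of [subject_dynamics()].
#' @export
cohort_dynamics <- function(paths, K, tr_seconds) {
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    id <- if (inherits(p, "state_path")) p$subject_id
          else names(paths)[[i]]
    subject_dynamics(p, K, tr_seconds,
                     subject_id = if (is.null(id)) paste0("sub", i) else id)
  })
  names(out) <- vapply(out, `[[`, character(1), "subject_id")
  out
}

#' Long-format dynamics table for a cohort
#'
#' One row per subject with fractional occupancy, lifetime and interval
#' columns per state plus the scalar switching rate; suitable for export.
#'
#' @param dyn list of [subject_dynamics()].
#' @return data.frame.
#' @export
dynamics_table <- function(dyn) {
  K <- length(dyn[[1L]]$fractional_occupancy)
  df <- data.frame(subject_id = vapply(dyn, `[[`, character(1),
                                       "subject_id"))
  for (k in seq_len(K))
    df[[sprintf("fo_state%d", k)]] <-
      vapply(dyn, function(d) d$fractional_occupancy[[k]], numeric(1))
  for (k in seq_len(K))
    df[[sprintf("lifetime_state%d", k)]] <-
      vapply(dyn, function(d) d$mean_lifetime[[k]], numeric(1))
  for (k in seq_len(K))
    df[[sprintf("interval_state%d", k)]] <-
      vapply(dyn, function(d) d$mean_interval[[k]], numeric(1))
  df$switching_rate <- vapply(dyn, `[[`, numeric(1), "switching_rate")
  rownames(df) <- NULL
  df
}
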
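# Internal numerical helpers shared across modules.

#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
#' @keywords internal
row_log_sum_exp <- function(x) {
  m <- apply(x, 1L, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-subject substream: results do not depend on cohort order.
# Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
subject_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647L)
}

#' @keywords internal
is_square_numeric <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x)
}

# Validate a row-stochastic matrix to tolerance.
#' @keywords internal
check_row_stochastic <- function(A, tol = 1e-12, what = "transition matrix") {
  if (!is_square_numeric(A)) stop(what, " must be a square numeric matrix")
  if (any(A < -tol)) stop(what, " has negative entries")
  rs <- rowSums(A)
  if (any(abs(rs - 1) > tol))
    stop(what, " rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  invisible(TRUE)
}

# Symmetric positive definite check via Cholesky.
#' @keywords internal
is_spd <- function(S, tol = 1e-10) {
  if (!is_square_numeric(S)) return(FALSE)
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) return(FALSE)
  !inherits(try(chol(S), silent = TRUE), "try-error")
}
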
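extract_metric <- function(dyn, metric, state) {
  vapply(dyn, function(d) switch(
    metric,
    fractional_occupancy = d$fractional_occupancy[[state]],
    lifetime = d$mean_lifetime[[state]],
    interval = d$mean_interval[[state]],
    switching_rate = d$switching_rate,
    stop("unknown metric '", metric, "'")), numeric(1))
}

#' Two-sample t tests over a dynamics metric, FDR-corrected
#'
#' For a per-state metric (fractional occupancy, lifetime, interval), one
#' two-tailed two-sample t test per state; for the scalar switching rate a
#' single global test. NaN values (unvisited states) are dropped pairwise
#' with the remaining group sizes recorded. Benjamini-Hochberg adjustment
#' is applied within the metric's family of K states.
#'
#' @param dynA,dynB lists of [subject_dynamics()] for the two groups.
#' @param metric one of `"fractional_occupancy"`, `"lifetime"`,
#'   `"interval"`, `"switching_rate"`.
#' @param variant `"student"` (pooled variance; default) or `"welch"`.
#' @param group_names length-2 character used in the output.
#' @return data.frame with one row per state (or one `"global"` row):
#'   metric, state, group means/SDs, t statistic, df, raw p, BH-adjusted q
#'   and per-group n after NaN exclusion. States with fewer than 2 usable
#'   values in a group get NA statistics and are excluded from the FDR
#'   family.
#' @export
compare_metric <- function(dynA, dynB, metric,
                           variant = c("student", "welch"),
                           group_names = c("A", "B")) {
  variant <- match.arg(variant)
  K <- length(dynA[[1L]]$fractional_occupancy)
  states <- if (metric == "switching_rate") NA_integer_ else seq_len(K)
  rows <- lapply(states, function(k) {
    a <- extract_metric(dynA, metric, k)
    b <- extract_metric(dynB, metric, k)
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    row <- data.frame(metric = metric,
                      state = if (is.na(k)) "global" else as.character(k),
                      mean_a = mean(a), mean_b = mean(b),
                      sd_a = stats::sd(a), sd_b = stats::sd(b),
                      t_statistic = NA_real_, df = NA_real_,
                      p_raw = NA_real_, q_fdr = NA_real_,
                      n_a = length(a), n_b = length(b))
    if (length(a) >= 2L && length(b) >= 2L) {
      tt <- stats::t.test(a, b, var.equal = (variant == "student"))
      row$t_statistic <- unname(tt$statistic)
      row$df <- unname(tt$parameter)
      row$p_raw <- tt$p.value
    }
    row
  })
  out <- do.call(rbind, rows)
  usable <- !is.na(out$p_raw)
  out$q_fdr[usable] <- fdr_adjust(out$p_raw[usable])
  names(out)[names(out) %in% c("mean_a", "mean_b", "sd_a", "sd_b",
                               "n_a", "n_b")] <-
    c(paste0("mean_", group_names), paste0("sd_", group_names),
      paste0("n_", group_names))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values: monotone, capped at 1, never below the raw p.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return numeric vector of q values.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Stack one transition entry across subjects, NaN-aware.
transition_entry <- function(dyn, i, j, view = "probs") {
  field <- if (view == "offdiag") "transition_probs_offdiag"
           else "transition_probs"
  vapply(dyn, function(d) d[[field]][i, j], numeric(1))
}

#' Label-permutation tests on transition probabilities
#'
#' For every ordered state pair, the observed statistic is the difference
#' of group means of the subject-level transition probability (group A
#' minus group B). The null distribution is built by shuffling group
#' labels; one shuffle per permutation serves all entries jointly, so the
#' dependence between entries is preserved. Two-sided p values use add-one
#' smoothing, `p = (1 + #{|null| >= |observed|}) / (n_permutations + 1)`,
#' so p is never exactly zero. Deterministic given `seed`.
#'
#' @param dynA,dynB lists of [subject_dynamics()] for the two groups.
#' @param n_permutations number of label shuffles (conventionally 5000).
#' @param seed integer seed.
#' @param include_diagonal test self-transitions too (default TRUE).
#' @param adjust also report BH-adjusted q values across the tested pairs
#'   (default TRUE; the raw p values remain the primary output).
#' @return data.frame with columns from, to, observed_diff, direction,
#'   p_perm, (q_fdr), n_permutations.
#' @export
permutation_test_transitions <- function(dynA, dynB,
                                         n_permutations = 5000L,
                                         seed = 1L,
                                         include_diagonal = TRUE,
                                         adjust = TRUE) {
  stopifnot(length(dynA) >= 1L, length(dynB) >= 1L)
  K <- nrow(dynA[[1L]]$transition_probs)
  nA <- length(dynA); nB <- length(dynB); n <- nA + nB
  pairs <- expand.grid(from = seq_len(K), to = seq_len(K))
  if (!include_diagonal) pairs <- pairs[pairs$from != pairs$to, ]
  # subjects x entries matrix of transition probabilities
  dyn_all <- c(dynA, dynB)
  X <- vapply(seq_len(nrow(pairs)), function(r)
    vapply(dyn_all, function(d)
      d$transition_probs[pairs$from[r], pairs$to[r]], numeric(1)),
    numeric(n))
  is_a <- c(rep(TRUE, nA), rep(FALSE, nB))
  grp_diff <- function(lab) {
    colMeans(X[lab, , drop = FALSE], na.rm = TRUE) -
      colMeans(X[!lab, , drop = FALSE], na.rm = TRUE)
  }
  observed <- grp_diff(is_a)
  exceed <- integer(length(observed))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      lab <- logical(n)
      lab[sample.int(n, nA)] <- TRUE
      nd <- grp_diff(lab)
      exceed <- exceed + (abs(nd) >= abs(observed) - 1e-15)
    }
  })
  p <- (1 + exceed) / (n_permutations + 1)
  out <- data.frame(from = pairs$from, to = pairs$to,
                    observed_diff = observed,
                    direction = ifelse(observed >= 0, "increase",
                                       "decrease"),
                    p_perm = p,
                    n_permutations = n_permutations)
  if (adjust) out$q_fdr <- fdr_adjust(out$p_perm)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted Spearman correlation
#'
#' Partial Spearman correlation between `x` and `y` given covariates:
#' both variables are rank-transformed, residualized on the covariates by
#' least squares (with intercept), and the Pearson correlation of the
#' residuals is the partial rank correlation. Continuous covariates are
#' rank-transformed too, for strictly rank-based partialing; binary
#' indicators (e.g. sex) are left as-is by ranking (ranks of a binary
#' variable are an affine map of it, so this is equivalent). The p value
#' uses the t approximation with `df = n - 2 - n_covariates`.
#'
#' @param x,y numeric vectors; pairs with any NA (in x, y or covariates)
#'   are dropped.
#' @param covariates optional numeric matrix / data.frame of covariates
#'   (columns such as age, sex indicator, education).
#' @return An object of class `correlation_result`: list with `rho`, `p`,
#'   `n`, `df`, `covariates` (names).
#' @examples
#' partial_spearman(1:5, c(2, 1, 4, 3, 5))$rho  # 0.7
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
    keep <- is.finite(x) & is.finite(y) &
      apply(covariates, 1L, function(r) all(is.finite(r)))
    covariates <- covariates[keep, , drop = FALSE]
  } else {
    keep <- is.finite(x) & is.finite(y)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < ncov + 3L)
    stop("need at least ", ncov + 3L, " complete pairs, got ", n)
  rx <- rank(x); ry <- rank(y)
  if (ncov > 0L) {
    rc <- apply(covariates, 2L, rank)
    qr_c <- qr(cbind(1, rc))
    if (qr_c$rank < ncov + 1L) stop("rank-deficient covariate matrix")
    rx <- qr.resid(qr_c, rx)
    ry <- qr.resid(qr_c, ry)
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - ncov
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df)
  structure(list(rho = rho, p = p, n = n, df = df,
                 covariates = colnames(covariates)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("partial Spearman rho =", format(x$rho, digits = 3),
      ", p =", format(x$p, digits = 3), ", n =", x$n, "\n")
  invisible(x)
}

#' Correlate per-state dynamics with a cognitive score
#'
#' Runs [partial_spearman()] between each state's value of a metric and a
#' score (e.g. MoCA), adjusted for the given covariate columns of the
#' metadata table.
#'
#' @param dyn list of [subject_dynamics()].
#' @param meta metadata data.frame aligned to `dyn` by `subject_id`.
#' @param metric metric name as in [compare_metric()].
#' @param score column of `meta` to correlate with (default `"moca"`).
#' @param covariate_cols columns of `meta` used as covariates; a character
#'   `sex` column is encoded as a 0/1 indicator.
#' @return data.frame with one row per state: metric, state, rho, p, n.
#' @export
correlate_with_score <- function(dyn, meta, metric, score = "moca",
                                 covariate_cols = c("age", "sex",
                                                    "education")) {
  ids <- vapply(dyn, `[[`, character(1), "subject_id")
  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  covs <- NULL
  if (length(covariate_cols)) {
    covs <- meta[, covariate_cols, drop = FALSE]
    for (cn in names(covs))
      if (!is.numeric(covs[[cn]]))
        covs[[cn]] <- as.numeric(factor(covs[[cn]])) - 1
  }
  K <- length(dyn[[1L]]$fractional_occupancy)
  states <- if (metric == "switching_rate") NA_integer_ else seq_len(K)
  rows <- lapply(states, function(k) {
    x <- extract_metric(dyn, metric, k)
    res <- try(partial_spearman(x, meta[[score]], covs), silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(metric = metric,
                 state = if (is.na(k)) "global" else as.character(k),
                 rho = NA_real_, p = NA_real_, n = sum(is.finite(x)))
    else
      data.frame(metric = metric,
                 state = if (is.na(k)) "global" else as.character(k),
                 rho = res$rho, p = res$p, n = res$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split subjects by cognitive-impairment cutoff on the MoCA
#'
#' Scores below 26 indicate cognitive impairment; scores above 26 normal
#' cognition. Scores exactly 26 are assigned to the unimpaired group and
#' counted in the returned boundary report.
#'
#' @param meta metadata data.frame with a `moca` column.
#' @param cutoff MoCA cutoff (default 26).
#' @return list with `impaired` and `unimpaired` character vectors of
#'   subject ids and `n_boundary`, the number of scores exactly at the
#'   cutoff.
#' @export
moca_impairment_groups <- function(meta, cutoff = 26) {
  if (!"moca" %in% names(meta)) stop("metadata has no moca column")
  m <- meta$moca
  ok <- is.finite(m)
  list(impaired = meta$subject_id[ok & m < cutoff],
       unimpaired = meta$subject_id[ok & m >= cutoff],
       n_boundary = sum(ok & m == cutoff))
}
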
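#' Per-state mean activation summary
#'
#' Thresholds a state's mean-activity vector (in standardized units) into
#' hyper-activated (`value > threshold`) and hypo-activated
#' (`value < -threshold`) region sets; inequalities are strict, so a
#' threshold of 0 classifies every nonzero region by sign.
#'
#' @param model an [hmm_model()].
#' @param state state index in 1..K.
#' @param threshold absolute activation threshold in standardized units
#'   (default 0.5).
#' @return An object of class `state_activation_map`: list with `state`,
#'   `region_values`, `region_labels`, `hyper_regions`, `hypo_regions`,
#'   `threshold`.
#' @export
activation_map <- function(model, state, threshold = 0.5) {
  stopifnot(inherits(model, "hmm_model"))
  if (state < 1L || state > model$n_states)
    stop("state ", state, " out of range 1..", model$n_states)
  labels <- model$region_labels
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(model$n_regions))
  v <- model$means[state, ]
  structure(
    list(state = as.integer(state),
         region_values = v,
         region_labels = labels,
         hyper_regions = labels[v > threshold],
         hypo_regions = labels[v < -threshold],
         threshold = threshold),
    class = "state_activation_map")
}

#' @export
print.state_activation_map <- function(x, ...) {
  cat("<state_activation_map> state", x$state, "(threshold",
      x$threshold, ")\n  hyper:",
      paste(x$hyper_regions, collapse = ", "), "\n  hypo: ",
      paste(x$hypo_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate a state's activation by user-supplied networks
#'
#' @param map a [activation_map()] result.
#' @param network_lookup data.frame with columns `region` and `network`;
#'   regions absent from the lookup are grouped under `"unassigned"`.
#' @return data.frame with per-network mean activation.
#' @export
network_activation <- function(map, network_lookup) {
  net <- network_lookup$network[match(map$region_labels,
                                      network_lookup$region)]
  net[is.na(net)] <- "unassigned"
  agg <- tapply(map$region_values, net, mean)
  data.frame(network = names(agg), mean_activation = as.numeric(agg))
}

#' Assemble a pipeline configuration
#'
#' Collects the knobs of every stage with their defaults. Either supply a
#' `simulate` block (a [ground_truth_spec()] or a `scale` for
#' [default_paper_like_spec()]) or an `input` block pointing at matrices
#' and metadata on disk.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global seed; stage seeds are derived from it.
#' @param simulate `NULL`, a [ground_truth_spec()], or a list with `scale`.
#' @param input `NULL` or list(`matrix_dir`, `meta_table`, `tr_seconds`).
#' @param standardize z-score each region per subject before fitting.
#' @param bandpass `NULL` or list(`low_hz`, `high_hz`).
#' @param K fixed number of states, or `NULL` to run order selection over
#'   `candidate_Ks`.
#' @param candidate_Ks candidates for order selection when `K` is `NULL`.
#' @param n_restarts,tol,max_iter EM settings (see [fit_hmm()]).
#' @param decoder `"gamma"` or `"viterbi"`.
#' @param n_permutations label shuffles for the transition tests.
#' @param alpha significance threshold for the summary report.
#' @param activation_threshold threshold for [activation_map()].
#' @param moca_cutoff impairment cutoff for the second contrast.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            input = NULL, standardize = TRUE,
                            bandpass = NULL, K = NULL,
                            candidate_Ks = c(2L, 3L, 4L),
                            n_restarts = 5L, tol = 1e-6, max_iter = 300L,
                            decoder = "gamma", n_permutations = 5000L,
                            alpha = 0.05, activation_threshold = 0.5,
                            moca_cutoff = 26) {
  if (is.null(simulate) && is.null(input))
    stop("config needs either a simulate block or an input block")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate or load a cohort, condition it, fit (or order-select) the HMM,
#' decode, compute per-subject dynamics, run both group contrasts
#' (patient vs control, impaired vs unimpaired by MoCA), permutation tests
#' on transition probabilities, covariate-adjusted correlations with the
#' MoCA score, and per-state activation maps. All tables are written under
#' `config$out_dir` together with the effective configuration and a
#' Markdown summary; the run is deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted model, dynamics, and all
#'   result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("R version: %s", getRversion()))

  # ingest
  if (!is.null(config$simulate)) {
    spec <- if (inherits(config$simulate, "ground_truth_spec"))
      config$simulate
    else default_paper_like_spec(scale = config$simulate$scale,
                                 seed = config$seed)
    sim <- simulate_cohort(spec)
    coh <- sim$cohort
    log_lines <- c(log_lines, sprintf("simulated cohort: %d subjects",
                                      n_subjects(coh)))
  } else {
    coh <- load_cohort(config$input$matrix_dir, config$input$meta_table,
                       tr_seconds = config$input$tr_seconds %||% 2)
    sim <- NULL
    log_lines <- c(log_lines, sprintf("loaded cohort: %d subjects",
                                      n_subjects(coh)))
  }
  if (!"group" %in% names(coh$meta))
    stop("stats stage requires a 'group' column in the metadata")

  # conditioning
  if (!is.null(config$bandpass))
    coh$series <- lapply(coh$series, bandpass_filter,
                         low_hz = config$bandpass$low_hz,
                         high_hz = config$bandpass$high_hz)
  if (isTRUE(config$standardize)) coh <- standardize_cohort(coh)

  # fit / order selection
  if (is.null(config$K)) {
    sel <- select_model_order(coh, config$candidate_Ks,
                              n_restarts = config$n_restarts,
                              seed = config$seed, tol = config$tol,
                              max_iter = config$max_iter)
    utils::write.table(sel$report,
                       file.path(config$out_dir, "order_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    K <- sel$chosen_K
    fit <- sel$fits[[paste0("K", K)]]
    log_lines <- c(log_lines, sprintf("order selection chose K = %d", K))
  } else {
    K <- config$K
    fit <- fit_hmm(coh, K, n_restarts = config$n_restarts,
                   seed = config$seed, tol = config$tol,
                   max_iter = config$max_iter,
                   decoder = config$decoder)
  }
  write_hmm_model(fit$model, file.path(config$out_dir, "hmm_model.json"))
  write_state_paths(fit$paths, file.path(config$out_dir, "state_paths"))

  # dynamics
  tr <- coh$series[[1L]]$tr_seconds
  dyn <- cohort_dynamics(fit$paths, K, tr)
  dtab <- dynamics_table(dyn)
  utils::write.table(dtab, file.path(config$out_dir, "dynamics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # contrasts
  meta <- coh$meta
  contrasts <- list()
  grp <- split(names(dyn), meta$group[match(names(dyn), meta$subject_id)])
  if (length(grp) == 2L) {
    gnames <- names(grp)
    dynA <- dyn[grp[[1L]]]; dynB <- dyn[grp[[2L]]]
    cmp <- do.call(rbind, lapply(
      c("fractional_occupancy", "lifetime", "interval", "switching_rate"),
      function(m) compare_metric(dynA, dynB, m, group_names = gnames)))
    perm <- permutation_test_transitions(
      dynA, dynB, n_permutations = config$n_permutations,
      seed = config$seed)
    contrasts[[paste(gnames, collapse = "_vs_")]] <-
      list(metrics = cmp, transitions = perm)
  }
  if ("moca" %in% names(meta) && any(is.finite(meta$moca))) {
    mg <- moca_impairment_groups(meta, config$moca_cutoff)
    if (length(mg$impaired) >= 2L && length(mg$unimpaired) >= 2L) {
      dynA <- dyn[mg$impaired]; dynB <- dyn[mg$unimpaired]
      cmp <- do.call(rbind, lapply(
        c("fractional_occupancy", "lifetime", "interval",
          "switching_rate"),
        function(m) compare_metric(dynA, dynB, m,
                                   group_names = c("impaired",
                                                   "unimpaired"))))
      perm <- permutation_test_transitions(
        dynA, dynB, n_permutations = config$n_permutations,
        seed = config$seed)
      contrasts$impaired_vs_unimpaired <-
        list(metrics = cmp, transitions = perm,
             n_boundary = mg$n_boundary)
    }
  }
  for (cn in names(contrasts)) {
    utils::write.table(
      contrasts[[cn]]$metrics,
      file.path(config$out_dir, paste0("metrics_", cn, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      contrasts[[cn]]$transitions,
      file.path(config$out_dir, paste0("transitions_", cn, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # correlations with cognition
  correlations <- NULL
  if ("moca" %in% names(meta) && any(is.finite(meta$moca))) {
    correlations <- do.call(rbind, lapply(
      c("fractional_occupancy", "lifetime", "interval"),
      function(m) correlate_with_score(dyn, meta, m)))
    utils::write.table(correlations,
                       file.path(config$out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # activation maps
  maps <- lapply(seq_len(K), activation_map, model = fit$model,
                 threshold = config$activation_threshold)
  map_tab <- do.call(rbind, lapply(maps, function(m)
    data.frame(state = m$state, region = m$region_labels,
               mean_activation = m$region_values,
               classification = ifelse(
                 m$region_values > m$threshold, "hyper",
                 ifelse(m$region_values < -m$threshold, "hypo", "none")))))
  utils::write.table(map_tab,
                     file.path(config$out_dir, "activation_maps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # effective config + summary
  cfg <- config
  cfg$simulate <- if (!is.null(config$simulate)) "<ground_truth_spec>"
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.atomic(v) || is.null(v)) v else "<object>"),
    file.path(config$out_dir, "effective_config.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  summary_md <- c(
    "# Pipeline summary", "",
    sprintf("- subjects: %d; states: %d; TR: %g s", n_subjects(coh), K,
            tr),
    sprintf("- contrasts run: %s",
            paste(names(contrasts), collapse = ", ")),
    vapply(names(contrasts), function(cn) {
      m <- contrasts[[cn]]$metrics
      sprintf("- %s: %d metric comparison(s) with q < %g", cn,
              sum(m$q_fdr < config$alpha, na.rm = TRUE), config$alpha)
    }, character(1)))
  writeLines(summary_md, file.path(config$out_dir, "summary.md"))

  invisible(list(model = fit$model, paths = fit$paths, dynamics = dyn,
                 dynamics_table = dtab, contrasts = contrasts,
                 correlations = correlations, maps = maps,
                 cohort = coh, ground_truth = sim))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
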
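# The two workflows: group-wise analysis and classification. Both share
# the identical correlation -> distance penalty -> thresholding -> metric
# code path; they differ only in how the modular decomposition is chosen
# (group consensus vs per-subject best).

#' Pipeline configuration
#'
#' Collects the tunable parameters of both workflows with the study
#' defaults: 12\% edge density, 10-35\% threshold sweep, 5 modules, q =
#' 0.05 with 1000 permutations, 6 features and 1000 bagging iterations.
#'
#' @param density Edge density for thresholding (default 0.12).
#' @param thresholds Sweep grid for global metrics.
#' @param k_modules Module count for constrained decompositions.
#' @param n_perm Label permutations for the FDR test.
#' @param n_iterations Bagging iterations.
#' @param n_features Features entering the SVM.
#' @param q FDR level.
#' @param n_restarts Louvain restarts per modularity run.
#' @param n_ref Random references per normalisation (0 disables).
#' @param balance_band Accepted training-set class share.
#' @param conditions Classification conditions to run.
#' @param run_sweep Whether the group workflow computes the threshold
#'   sweep (the expensive normalised-metric curve).
#' @param seed Root seed; all stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(density = 0.12,
                            thresholds = seq(0.10, 0.35, by = 0.01),
                            k_modules = 5, n_perm = 1000,
                            n_iterations = 1000, n_features = 6,
                            q = 0.05, n_restarts = 20, n_ref = 20,
                            balance_band = c(0.4, 0.6),
                            conditions = c("actual", "pre_shuffle",
                                           "post_shuffle"),
                            run_sweep = FALSE, seed = 1) {
  stopifnot(density > 0, density <= 1, all(thresholds > 0),
            all(thresholds <= 1), k_modules >= 2, n_perm >= 2,
            n_iterations >= 1, n_features >= 1, q > 0, q < 1,
            n_restarts >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# Shared front end: correlations, distance models and penalized matrices.
prepare_connectivity <- function(cohort) {
  parc <- cohort$parcellation
  conns <- purrr::map(cohort$subjects, compute_correlation)
  models <- purrr::map(conns, fit_distance_trend, parcellation = parc)
  penalized <- purrr::map2(conns, models, apply_distance_penalty,
                           parcellation = parc)
  list(raw = conns, models = models, penalized = penalized,
       labels = purrr::map_chr(cohort$subjects, function(s) s$group),
       ids = purrr::map_chr(cohort$subjects, function(s) s$subject_id))
}

#' Run the group-wise analysis workflow
#'
#' Correlation, distance penalty, group-consensus modular decomposition,
#' thresholding, participation ranks, node-wise permutation-FDR tests,
#' the global-signal control, and (optionally) the normalised
#' global-metric threshold sweep with pooled AUC tests.
#'
#' @param cohort A `cohort` (from [simulate_cohort()] or [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param outdir Optional directory for result tables.
#' @return A list of class `group_analysis`: `consensus` partition,
#'   `pi_ranks` (subjects x nodes), `node_tests` (`group_test_result`),
#'   `residual_test`, `global_signal_test`, `curves` and `curve_tests`
#'   (when `run_sweep`), and `labels`.
#' @export
run_group_analysis <- function(cohort, config = pipeline_config(),
                               outdir = NULL) {
  prep <- prepare_connectivity(cohort)
  groups <- prep$labels
  residual_test <- compare_residual_errors(
    prep$models[groups == "control"], prep$models[groups == "patient"])

  consensus <- group_consensus_partition(
    prep$penalized, k_target = config$k_modules,
    seed = derive_seed(config$seed, 11L), n_restarts = config$n_restarts)

  graphs <- purrr::map(prep$penalized, threshold_graph,
                       density = config$density)
  pis <- purrr::map(graphs, participation_index, partition = consensus)
  pi_ranks <- do.call(rbind, purrr::map(pis, function(p) p$rank))
  colnames(pi_ranks) <- pis[[1]]$region
  rownames(pi_ranks) <- prep$ids

  node_tests <- resampling_fdr(pi_ranks, groups, n_perm = config$n_perm,
                               q = config$q,
                               seed = derive_seed(config$seed, 13L))
  gs_test <- compare_global_signal(cohort$subjects, groups)

  curves <- curve_tests <- NULL
  if (isTRUE(config$run_sweep)) {
    curves <- purrr::imap_dfr(prep$penalized, function(pen, i) {
      dplyr::mutate(
        metric_threshold_curve(pen, thresholds = config$thresholds,
                               n_ref = config$n_ref,
                               seed = derive_seed(config$seed, 100L + i)),
        subject_id = prep$ids[i])
    })
    curve_tests <- global_metric_tests(
      curves, stats::setNames(groups, prep$ids))
  }

  out <- structure(
    list(consensus = consensus, pi_ranks = pi_ranks,
         node_tests = node_tests, residual_test = residual_test,
         global_signal_test = gs_test, curves = curves,
         curve_tests = curve_tests, labels = groups, config = config),
    class = "group_analysis")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tibble::as_tibble(node_tests),
                     file.path(outdir, "node_tests.csv"))
    write_partition(consensus, file.path(outdir, "consensus_partition.csv"))
    jsonlite::write_json(
      list(n_significant = sum(node_tests$significant),
           n_up = sum(node_tests$significant &
                        node_tests$direction == "up"),
           n_down = sum(node_tests$significant &
                          node_tests$direction == "down"),
           residual_p = residual_test$p_value,
           global_signal_p = gs_test$p_value),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(curves)) {
      readr::write_csv(curves, file.path(outdir, "metric_curves.csv"))
      readr::write_csv(curve_tests, file.path(outdir, "curve_tests.csv"))
    }
  }
  out
}

#' @export
print.group_analysis <- function(x, ...) {
  nt <- x$node_tests
  cat(sprintf(
    "<group_analysis> %d nodes tested; %d significant (%d down, %d up) at q = %g\n",
    nrow(nt), sum(nt$significant),
    sum(nt$significant & nt$direction == "down"),
    sum(nt$significant & nt$direction == "up"), attr(nt, "q")))
  invisible(x)
}

#' Compute the per-subject feature matrix of a cohort
#'
#' The classification front end: per subject, threshold the penalized
#' matrix, compute node metrics, find the subject's own best `k_modules`
#' decomposition on the full signed matrix, and take participation from
#' the thresholded graph under that individual partition.
#'
#' @inheritParams run_group_analysis
#' @return A `feature_matrix`.
#' @export
cohort_features <- function(cohort, config = pipeline_config()) {
  prep <- prepare_connectivity(cohort)
  graphs <- purrr::map(prep$penalized, threshold_graph,
                       density = config$density)
  metric_tables <- purrr::map(graphs, node_metrics)
  pi_tables <- purrr::map(seq_along(graphs), function(i) {
    part <- best_partition(prep$penalized[[i]],
                           n_restarts = config$n_restarts,
                           seed = derive_seed(config$seed, 300L + i),
                           k_target = config$k_modules)
    participation_index(graphs[[i]], part)
  })
  names(metric_tables) <- names(pi_tables) <- prep$ids
  build_feature_matrix(metric_tables, pi_tables, prep$labels)
}

#' Run the classification workflow
#'
#' Per-subject best 5-module decompositions feed the feature matrix; mRMR
#' ranks features inside each bagging split; a linear SVM is trained and
#' scored under the requested conditions (actual / pre-shuffle /
#' post-shuffle).
#'
#' @inheritParams run_group_analysis
#' @param k_curve Optional feature-count grid; when given, a
#'   [feature_count_curve()] is computed under the actual condition.
#' @return A list of class `classification_analysis`: `features`,
#'   `reports` (one `classification_report` per condition), `ranking`
#'   (mRMR on the full cohort, for description), and optionally `curve`.
#' @export
run_classification <- function(cohort, config = pipeline_config(),
                               outdir = NULL, k_curve = NULL) {
  features <- cohort_features(cohort, config)
  reports <- purrr::map(config$conditions, function(cond) {
    bagged_classification(features, n_features = config$n_features,
                          n_iterations = config$n_iterations,
                          condition = cond,
                          seed = derive_seed(config$seed,
                                             match(cond, c("actual",
                                                           "pre_shuffle",
                                                           "post_shuffle"))),
                          balance_band = config$balance_band)
  })
  names(reports) <- config$conditions
  ranking <- mrmr_rank(features, n_select = min(25L, ncol(features$x)))
  curve <- NULL
  if (!is.null(k_curve)) {
    curve <- feature_count_curve(features, k_values = k_curve,
                                 n_iterations = config$n_iterations,
                                 seed = derive_seed(config$seed, 4L),
                                 balance_band = config$balance_band)
  }
  out <- structure(list(features = features, reports = reports,
                        ranking = ranking, curve = curve, config = config),
                   class = "classification_analysis")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      purrr::map(reports, function(r) as.list(r$summary)),
      file.path(outdir, "classification_summary.json"),
      auto_unbox = TRUE, digits = NA)
    readr::write_csv(ranked_feature_table(ranking),
                     file.path(outdir, "feature_ranking.csv"))
    if (!is.null(curve)) {
      readr::write_csv(curve, file.path(outdir, "feature_curve.csv"))
    }
  }
  out
}

#' @export
print.classification_analysis <- function(x, ...) {
  cat("<classification_analysis>\n")
  for (r in x$reports) print(r$summary)
  invisible(x)
}

#' Tabulate a ranked feature list
#'
#' @param ranking Character vector of `"metric:region"` names (e.g. from
#'   [mrmr_rank()]).
#' @return A tibble: `rank`, `metric`, `region`.
#' @export
ranked_feature_table <- function(ranking) {
  parts <- strsplit(as.character(ranking), ":", fixed = TRUE)
  tibble::tibble(rank = seq_along(ranking),
                 metric = purrr::map_chr(parts, 1),
                 region = purrr::map_chr(parts, ~ paste(.x[-1],
                                                        collapse = ":")))
}
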
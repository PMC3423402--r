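# Between-group statistics on node-wise participation ranks, global metric
# curves, and the global signal.

# Vectorised Welch t over the columns of `x` (subjects x nodes), given a
# logical vector marking group A rows. Zero pooled SE: t = 0, p = 1 when
# means agree, +-Inf / 0 otherwise.
welch_t_columns <- function(x, is_a) {
  xa <- x[is_a, , drop = FALSE]
  xb <- x[!is_a, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(sweep(xa, 2, ma)^2) / (na - 1) / na
  vb <- colSums(sweep(xb, 2, mb)^2) / (nb - 1) / nb
  se <- sqrt(va + vb)
  diff <- ma - mb
  tt <- ifelse(se > 0, diff / se,
               ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se > 0,
               (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1)), 1)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tt), df),
              ifelse(diff == 0, 1, 0))
  list(statistic = unname(tt), p_value = unname(p), diff = unname(diff))
}

as_subject_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  as.matrix(as.data.frame(data))
}

#' Node-wise between-group test on participation ranks
#'
#' Welch two-sample t-test per node, two-sided, on within-subject PI ranks.
#' Direction is the sign of (patient mean - control mean).
#'
#' @param ranks Subjects x nodes matrix (or data frame) of PI ranks, e.g.
#'   rows of [rank_pi()] output.
#' @param labels Character/factor vector per subject, values `"control"` /
#'   `"patient"`.
#' @return A tibble: `node`, `region`, `statistic`, `p_raw`, `direction`.
#' @export
nodewise_group_test <- function(ranks, labels) {
  x <- as_subject_matrix(ranks)
  labels <- as.character(labels)
  if (min(table(labels)) < 2 || length(unique(labels)) != 2) {
    abort("two groups with at least 2 subjects each are required.",
          class = "brainmod_insufficient_data")
  }
  is_pat <- labels == "patient"
  ht <- welch_t_columns(x, is_pat)
  tibble::tibble(
    node = seq_len(ncol(x)),
    region = colnames(x) %||% as.character(seq_len(ncol(x))),
    statistic = ht$statistic,
    p_raw = ht$p_value,
    direction = ifelse(ht$diff >= 0, "up", "down")
  )
}

#' Permutation-based FDR-corrected node-wise test
#'
#' Observed Welch t statistics per node are referred to a permutation null
#' built from `n_perm` random relabellings of the subjects; the permuted
#' statistics are pooled across nodes and permutations (the statistics are
#' studentised and hence comparable across nodes), giving each node a
#' permutation p-value with resolution 1/(n_perm x N + 1). The p-values are
#' then adjusted by Benjamini-Hochberg step-up at level `q`.
#'
#' @param data Subjects x nodes matrix (typically PI ranks).
#' @param labels Group labels per subject (`"control"` / `"patient"`).
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed.
#' @return A tibble of class `group_test_result`: `node`, `region`,
#'   `t_statistic`, `p_raw` (permutation p), `p_adjusted`, `direction`,
#'   `significant`; attributes `q` and `n_perm`.
#' @export
resampling_fdr <- function(data, labels, n_perm = 1000, q = 0.05,
                           seed = 1) {
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  if (n_perm < 2) abort("`n_perm` must be at least 2.")
  x <- as_subject_matrix(data)
  labels <- as.character(labels)
  is_pat <- labels == "patient"
  obs <- welch_t_columns(x, is_pat)
  n_node <- ncol(x)
  null_abs <- with_seed(derive_seed(seed, 7L), {
    out <- matrix(0, n_perm, n_node)
    for (b in seq_len(n_perm)) {
      out[b, ] <- abs(welch_t_columns(x, sample(is_pat))$statistic)
    }
    out
  })
  pool <- sort(as.numeric(null_abs))
  n_pool <- length(pool)
  # p_i = (1 + #{null >= |t_i|}) / (1 + pool size), via binary search
  ge <- n_pool - findInterval(abs(obs$statistic) - 1e-12, pool)
  p_raw <- (1 + ge) / (1 + n_pool)
  if (min(p_raw) > q / n_node) {
    min_attainable <- 1 / (1 + n_pool)
    if (min_attainable > q / n_node) {
      warn(sprintf(
        "permutation resolution %.2g may be too coarse for BH at q = %g over %d nodes",
        min_attainable, q, n_node))
    }
  }
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  out <- tibble::tibble(
    node = seq_len(n_node),
    region = colnames(x) %||% as.character(seq_len(n_node)),
    t_statistic = obs$statistic,
    p_raw = p_raw,
    p_adjusted = p_adj,
    direction = ifelse(obs$diff >= 0, "up", "down"),
    significant = p_adj <= q
  )
  class(out) <- c("group_test_result", class(out))
  attr(out, "q") <- q
  attr(out, "n_perm") <- n_perm
  out
}

#' Between-group tests on global metric curves
#'
#' Welch t-tests per threshold for each metric, plus a pooled test on
#' subject-wise areas under the curve.
#'
#' @param curves A tibble binding every subject's
#'   [metric_threshold_curve()] with a `subject_id` column; all subjects
#'   must share the same threshold grid.
#' @param labels Named group labels (names = subject ids), or a vector in
#'   the order subjects first appear in `curves`.
#' @param metrics Metric columns to test (default `c("PL", "CC", "SWI")`).
#' @return A tibble: `metric`, `test` (`"per_threshold"` or
#'   `"pooled_auc"`), `threshold` (NA for pooled rows), `statistic`,
#'   `p_value`.
#' @export
global_metric_tests <- function(curves, labels,
                                metrics = c("PL", "CC", "SWI")) {
  ids <- unique(curves$subject_id)
  if (is.null(names(labels))) names(labels) <- ids
  grids <- purrr::map(ids, ~ sort(curves$threshold[curves$subject_id == .x]))
  if (length(unique(purrr::map_chr(grids, paste, collapse = ","))) != 1L) {
    abort("all subjects must share one threshold grid.",
          class = "brainmod_shape")
  }
  is_pat <- as.character(labels[ids]) == "patient"
  purrr::map_dfr(metrics, function(m) {
    wide <- do.call(rbind, purrr::map(ids, function(id) {
      sub <- curves[curves$subject_id == id, ]
      sub[[m]][order(sub$threshold)]
    }))
    thr <- sort(unique(curves$threshold))
    per <- welch_t_columns(wide, is_pat)
    aucs <- purrr::map_dbl(ids, function(id) {
      curve_auc(curves[curves$subject_id == id, ], metric = m)
    })
    pooled <- welch_t(aucs[is_pat], aucs[!is_pat])
    dplyr::bind_rows(
      tibble::tibble(metric = m, test = "per_threshold", threshold = thr,
                     statistic = per$statistic, p_value = per$p_value),
      tibble::tibble(metric = m, test = "pooled_auc",
                     threshold = NA_real_, statistic = pooled$statistic,
                     p_value = pooled$p_value)
    )
  })
}

#' Between-group comparison of the global signal
#'
#' For each subject the global signal is the mean across regions at each
#' time point; its temporal standard deviation summarises the subject (the
#' series are zero-mean, so the temporal mean is uninformative). Groups are
#' compared by Welch t-test on that scalar.
#'
#' @param subjects A `cohort`, or a list of `roi_ts` objects.
#' @param labels Optional group labels (taken from the subjects when
#'   omitted).
#' @return A tibble: `statistic`, `p_value`, `mean_control`,
#'   `mean_patient`, `df`.
#' @export
compare_global_signal <- function(subjects, labels = NULL) {
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  if (is.null(labels)) {
    labels <- purrr::map_chr(subjects, function(s) s$group)
  }
  if (min(table(labels)) < 2) {
    abort("at least 2 subjects per group are required.",
          class = "brainmod_insufficient_data")
  }
  gs <- purrr::map_dbl(subjects, function(s) {
    x <- if (inherits(s, "roi_ts")) s$data else as.matrix(s)
    stats::sd(rowMeans(x))
  })
  is_pat <- as.character(labels) == "patient"
  ht <- welch_t(gs[is_pat], gs[!is_pat])
  tibble::tibble(statistic = ht$statistic, p_value = ht$p_value,
                 mean_control = mean(gs[!is_pat]),
                 mean_patient = mean(gs[is_pat]), df = ht$df)
}
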
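# Feature assembly, mRMR / RFE ranking, balanced splits and the bagged
# linear-SVM protocol with label-shuffle controls.

feature_metric_order <- c("PI", "degree", "strength", "BC", "CC_node",
                          "LE_node", "GE_node", "LEGE")

#' Assemble the subjects-by-features matrix
#'
#' One column per (metric, node) pair over the 8 node-wise metrics
#' (participation index, degree, strength, betweenness, clustering, local
#' and global nodal efficiency, and their ratio), metric-major with node
#' index minor; names are `"metric:region"`. Participation columns come
#' from each subject's own best 5-module decomposition, the remaining
#' metrics from the thresholded graph.
#'
#' @param metric_tables Named list (by subject) of [node_metrics()]
#'   tibbles.
#' @param pi_tables Named list (by subject) of [participation_index()]
#'   tibbles.
#' @param labels Group labels in the same subject order.
#' @return A list of class `feature_matrix`: `x` (subjects x features
#'   numeric matrix), `labels` (factor control/patient), `subjects`.
#' @export
build_feature_matrix <- function(metric_tables, pi_tables, labels) {
  stopifnot(length(metric_tables) == length(pi_tables),
            length(labels) == length(metric_tables))
  regions <- metric_tables[[1]]$region
  rows <- purrr::map(seq_along(metric_tables), function(i) {
    mt <- metric_tables[[i]]
    pv <- pi_tables[[i]]
    if (!identical(mt$region, regions) || !identical(pv$region, regions)) {
      abort("inconsistent node sets across subjects.",
            class = "brainmod_completeness")
    }
    vals <- purrr::map(feature_metric_order, function(m) {
      if (m == "PI") pv$pi else mt[[m]]
    })
    unlist(vals)
  })
  x <- do.call(rbind, rows)
  colnames(x) <- unlist(purrr::map(feature_metric_order,
                                   ~ paste0(.x, ":", regions)))
  if (anyNA(x)) abort("missing metric values.",
                      class = "brainmod_completeness")
  subjects <- names(metric_tables) %||% sprintf("sub%03d", seq_len(nrow(x)))
  rownames(x) <- subjects
  structure(list(x = x, labels = factor(as.character(labels),
                                        levels = c("control", "patient")),
                 subjects = subjects),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(levels(x$labels), table(x$labels), collapse = " / ")))
  invisible(x)
}

# 3-bin discretisation at mean +- SD, columnwise; integer codes 0..2.
# Population (1/n) SD with closed outer intervals, so a two-valued feature
# falls into the outer bins rather than collapsing into the middle one.
discretize_features <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  lo <- sweep(x, 2, m - s + 1e-12, "<")
  hi <- sweep(x, 2, m + s - 1e-12, ">")
  d <- matrix(1L, nrow(x), ncol(x))
  d[lo] <- 0L
  d[hi] <- 2L
  dimnames(d) <- dimnames(x)
  d
}

# Mutual information (nats) between an integer vector `v` and each column
# of integer matrix `d`; both coded 0..2 (v may be 0..1 for labels).
mi_columns <- function(d, v) {
  n <- length(v)
  mi <- numeric(ncol(d))
  for (a in sort(unique(v))) {
    rows <- v == a
    pa <- sum(rows) / n
    for (b in 0:2) {
      nab <- colSums(d[rows, , drop = FALSE] == b) / n
      pb <- colSums(d == b) / n
      term <- nab * log(nab / (pa * pb))
      term[nab == 0] <- 0
      mi <- mi + term
    }
  }
  mi
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mutual-information-difference (MID) selection: features are
#' discretised into 3 bins at mean +- SD; the first feature maximises
#' mutual information with the class label, and each subsequent feature
#' maximises relevance minus the mean mutual information with the features
#' already selected.
#'
#' @param features A `feature_matrix` or plain numeric matrix.
#' @param labels Class labels (ignored when `features` is a
#'   `feature_matrix`... pass explicitly to override).
#' @param n_select Number of features to rank.
#' @return Character vector of selected column names, best first, with
#'   attribute `scores` (the greedy MID score at selection).
#' @export
mrmr_rank <- function(features, labels = NULL, n_select = 6) {
  x <- if (inherits(features, "feature_matrix")) features$x else
    as.matrix(features)
  if (is.null(labels) && inherits(features, "feature_matrix")) {
    labels <- features$labels
  }
  if (n_select > ncol(x)) abort("`n_select` exceeds the feature count.")
  d <- discretize_features(x)
  y <- as.integer(factor(labels)) - 1L
  relevance <- mi_columns(d, y)
  selected <- integer(0)
  scores <- numeric(0)
  redundancy <- rep(0, ncol(x))
  for (k in seq_len(n_select)) {
    crit <- relevance - if (k == 1) 0 else redundancy / (k - 1)
    crit[selected] <- -Inf
    pick <- unname(which.max(crit))
    selected <- c(selected, pick)
    scores <- c(scores, unname(crit[pick]))
    if (k < n_select) {
      redundancy <- redundancy + mi_columns(d, d[, pick])
    }
  }
  out <- colnames(x)[selected] %||% as.character(selected)
  attr(out, "scores") <- scores
  attr(out, "index") <- selected
  out
}

#' Recursive feature elimination ranking with a linear SVM
#'
#' Trains a linear SVM (C = 1) on standardised features and iteratively
#' removes the feature with the smallest absolute weight, one per round;
#' the survivor is ranked first.
#'
#' @inheritParams mrmr_rank
#' @return Character vector of all feature names, best first.
#' @export
rfe_rank <- function(features, labels = NULL) {
  x <- if (inherits(features, "feature_matrix")) features$x else
    as.matrix(features)
  if (is.null(labels) && inherits(features, "feature_matrix")) {
    labels <- features$labels
  }
  if (ncol(x) < 2) abort("at least 2 features are required.")
  y <- factor(labels)
  xs <- scale(x)
  xs[, apply(x, 2, stats::sd) == 0] <- 0
  alive <- seq_len(ncol(x))
  eliminated <- integer(0)
  while (length(alive) > 1L) {
    fit <- e1071::svm(xs[, alive, drop = FALSE], y, kernel = "linear",
                      cost = 1, scale = FALSE)
    wvec <- t(fit$coefs) %*% fit$SV
    drop_i <- which.min(abs(as.numeric(wvec)))
    eliminated <- c(alive[drop_i], eliminated)
    alive <- alive[-drop_i]
  }
  colnames(x)[c(alive, eliminated)]
}

#' Draw a balanced random half split
#'
#' Random 50/50 train/test split, redrawn until each class's share of the
#' training set (and, symmetrically, of the test set) lies within
#' `balance_band`; heavily imbalanced splits are discarded.
#'
#' @param labels Class labels per subject (>= 4 subjects).
#' @param seed Integer seed.
#' @param balance_band Length-2 accepted range of the patient share
#'   (default `c(0.4, 0.6)`).
#' @param max_tries Redraw limit before erroring.
#' @return A list of class `split_scheme`: `train`, `test` (index
#'   vectors), `n_rejected`.
#' @export
make_split <- function(labels, seed = 1, balance_band = c(0.4, 0.6),
                       max_tries = 10000) {
  n <- length(labels)
  if (n < 4) abort("at least 4 subjects are required.")
  is_pat <- as.character(labels) == levels(factor(labels))[2]
  with_seed(seed, {
    rejected <- 0L
    for (try in seq_len(max_tries)) {
      n_train <- if (n %% 2L == 0L) n %/% 2L else
        n %/% 2L + sample(0:1, 1)
      train <- sort(sample.int(n, n_train))
      sh_tr <- mean(is_pat[train])
      sh_te <- mean(is_pat[-train])
      if (sh_tr >= balance_band[1] && sh_tr <= balance_band[2] &&
          sh_te >= balance_band[1] && sh_te <= balance_band[2]) {
        return(structure(list(train = train,
                              test = setdiff(seq_len(n), train),
                              n_rejected = rejected),
                         class = "split_scheme"))
      }
      rejected <- rejected + 1L
    }
    abort("no split satisfied the balance band.",
          class = "brainmod_config")
  })
}

rate_pair <- function(pred, truth) {
  ctrl <- truth == "control"
  pat <- truth == "patient"
  c(selectivity = if (any(ctrl)) mean(pred[ctrl] == "control") else NA_real_,
    sensitivity = if (any(pat)) mean(pred[pat] == "patient") else NA_real_)
}

#' Bagged linear-SVM classification with shuffle controls
#'
#' The Table-2-style protocol: at each iteration a balanced random half
#' split is drawn; features are ranked by [mrmr_rank()] on the training
#' half only, standardised by training statistics, and a linear SVM
#' (C = 1) is trained on the top `n_features`. Conditions: `"actual"` uses
#' true labels throughout; `"pre_shuffle"` permutes all labels before
#' feature selection and training (a full permutation null); and
#' `"post_shuffle"` trains on true labels but scores the test half against
#' permuted test labels. Selectivity is specificity (correct controls /
#' all controls) and sensitivity the true-patient rate.
#'
#' @param features A `feature_matrix`.
#' @param n_features Number of selected features (default 6).
#' @param n_iterations Number of bagging iterations (default 1000).
#' @param condition `"actual"`, `"pre_shuffle"` or `"post_shuffle"`.
#' @param seed Integer seed.
#' @param balance_band Passed to [make_split()].
#' @return A list of class `classification_report`: `condition`,
#'   `n_features`, `n_iterations`, `iterations` (per-iteration tibble) and
#'   `summary` (one-row tibble of means).
#' @export
bagged_classification <- function(features, n_features = 6,
                                  n_iterations = 1000,
                                  condition = c("actual", "pre_shuffle",
                                                "post_shuffle"),
                                  seed = 1, balance_band = c(0.4, 0.6)) {
  condition <- match.arg(condition)
  if (n_features < 1) abort("`n_features` must be at least 1.")
  if (n_iterations < 1) abort("`n_iterations` must be at least 1.")
  x <- features$x
  truth <- as.character(features$labels)
  n <- nrow(x)
  rows <- vector("list", n_iterations)
  skipped <- 0L
  for (it in seq_len(n_iterations)) {
    sp <- make_split(truth, seed = derive_seed(seed, 2L * it),
                     balance_band = balance_band)
    lab <- truth
    if (condition == "pre_shuffle") {
      lab <- with_seed(derive_seed(seed, 2L * it + 1L), sample(truth))
    }
    tr_lab <- lab[sp$train]
    if (length(unique(tr_lab)) < 2L) {
      skipped <- skipped + 1L
      next
    }
    sel <- attr(mrmr_rank(x[sp$train, , drop = FALSE], tr_lab,
                          n_select = n_features), "index")
    xt <- x[sp$train, sel, drop = FALSE]
    mu <- colMeans(xt)
    sdv <- apply(xt, 2, stats::sd)
    sdv[sdv == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(std(xt), factor(tr_lab,
                                      levels = c("control", "patient")),
                      kernel = "linear", cost = 1, scale = FALSE)
    pred_tr <- as.character(stats::predict(fit, std(xt)))
    pred_te <- as.character(stats::predict(
      fit, std(x[sp$test, sel, drop = FALSE])))
    eval_tr <- lab[sp$train]
    eval_te <- switch(condition,
      actual = truth[sp$test],
      pre_shuffle = lab[sp$test],
      post_shuffle = with_seed(derive_seed(seed, 2L * it + 1L),
                               sample(truth[sp$test]))
    )
    rtr <- rate_pair(pred_tr, eval_tr)
    rte <- rate_pair(pred_te, eval_te)
    rows[[it]] <- tibble::tibble(
      iteration = it,
      train_selectivity = rtr[["selectivity"]],
      train_sensitivity = rtr[["sensitivity"]],
      test_selectivity = rte[["selectivity"]],
      test_sensitivity = rte[["sensitivity"]],
      n_rejected_splits = sp$n_rejected
    )
  }
  iterations <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    condition = condition, n_features = n_features,
    n_iterations = nrow(iterations),
    train_selectivity = mean(iterations$train_selectivity, na.rm = TRUE),
    train_sensitivity = mean(iterations$train_sensitivity, na.rm = TRUE),
    test_selectivity = mean(iterations$test_selectivity, na.rm = TRUE),
    test_sensitivity = mean(iterations$test_sensitivity, na.rm = TRUE)
  )
  structure(list(condition = condition, n_features = n_features,
                 n_iterations = n_iterations, n_skipped = skipped,
                 iterations = iterations, summary = summary),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> condition = %s, %d features, %d iterations\n",
              x$condition, x$n_features, x$n_iterations))
  print(x$summary)
  invisible(x)
}

#' Classification performance across feature counts
#'
#' Runs [bagged_classification()] at each feature count and collects the
#' mean rates, tracing how accuracy grows with the number of selected
#' features.
#'
#' @inheritParams bagged_classification
#' @param k_values Feature counts to evaluate (default 1..25).
#' @return A tibble of class `feature_curve`: one row per k with mean
#'   train/test selectivity and sensitivity.
#' @export
feature_count_curve <- function(features, k_values = 1:25,
                                n_iterations = 100,
                                condition = "actual", seed = 1,
                                balance_band = c(0.4, 0.6)) {
  if (length(k_values) < 1) abort("`k_values` must be nonempty.")
  out <- purrr::map_dfr(k_values, function(k) {
    rep <- bagged_classification(features, n_features = k,
                                 n_iterations = n_iterations,
                                 condition = condition,
                                 seed = derive_seed(seed, 10000L + k),
                                 balance_band = balance_band)
    rep$summary
  })
  out <- dplyr::rename(out, k = "n_features")
  class(out) <- c("feature_curve", class(out))
  out
}
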
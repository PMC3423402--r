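toy_features <- function(n_per = 12, seed = 1, gap = 3, n_signal = 2) {
  set.seed(seed)
  n <- 2 * n_per
  x <- matrix(rnorm(n * 8), n, 8)
  x[(n_per + 1):n, seq_len(n_signal)] <-
    x[(n_per + 1):n, seq_len(n_signal)] + gap
  colnames(x) <- paste0("F", 1:8)
  rownames(x) <- sprintf("s%02d", 1:n)
  structure(list(x = x,
                 labels = factor(rep(c("control", "patient"),
                                     each = n_per)),
                 subjects = rownames(x)),
            class = "feature_matrix")
}

test_that("feature matrices have metric-major named columns", {
  co <- tiny_cohort(seed = 17, n_control = 2, n_patient = 2,
                    n_regions = 10, n_timepoints = 60, n_down = 1,
                    n_up = 1)
  fm <- cohort_features(co, pipeline_config(k_modules = 3, n_restarts = 3,
                                            seed = 2))
  expect_equal(ncol(fm$x), 8 * 10)
  expect_equal(nrow(fm$x), 4)
  regions <- co$parcellation$region
  expect_equal(colnames(fm$x)[1], paste0("PI:", regions[1]))
  expect_equal(colnames(fm$x)[11], paste0("degree:", regions[1]))
  expect_false(any(duplicated(colnames(fm$x))))
  expect_false(anyNA(fm$x))
  # named lookup returns that node's participation
  g <- threshold_graph({
    conn <- compute_correlation(co$subjects[[1]])
    apply_distance_penalty(conn, fit_distance_trend(conn, co$parcellation),
                           co$parcellation)
  }, 0.12)
  # identical subject inputs give identical rows
  fm2 <- build_feature_matrix(
    list(a = node_metrics(g), b = node_metrics(g)),
    list(a = participation_index(g, rep(1:2, each = 5)),
         b = participation_index(g, rep(1:2, each = 5))),
    c("control", "patient"))
  expect_equal(fm2$x[1, ], fm2$x[2, ])
  expect_equal(unname(fm2$x[1, paste0("PI:", regions[3])]),
               participation_index(g, rep(1:2, each = 5))$pi[3])
})

test_that("mRMR ranks a label-identical feature first, not its duplicate", {
  set.seed(40)
  n <- 30
  y <- rep(c("control", "patient"), each = n / 2)
  x <- cbind(signal = ifelse(y == "patient", 1, -1) + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 5), n, 5))
  colnames(x) <- c("signal", paste0("noise", 1:5))
  expect_equal(mrmr_rank(x, y, n_select = 1)[1], "signal")
  xdup <- cbind(x, dup = x[, "signal"])
  r2 <- mrmr_rank(xdup, y, n_select = 2)
  expect_true(r2[1] %in% c("signal", "dup"))
  expect_false(r2[2] %in% c("signal", "dup"))
})

test_that("greedy mRMR equals the independent MID ranking on 3-feature toys", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 24
    y <- rep(c(0L, 1L), each = n / 2)
    x <- cbind(a = y + rnorm(n, 0, 0.8), b = rnorm(n),
               c = y * rnorm(n, 1, 0.5) + rnorm(n, 0, 0.6))
    got <- attr(mrmr_rank(x, y, n_select = 3), "index")
    d <- brainmod:::discretize_features(x)
    want <- indep_mid_order(d, y, 3)
    expect_equal(got, want, label = sprintf("seed %d", seed))
  }
})

test_that("RFE keeps the informative feature to the end, deterministically", {
  set.seed(41)
  n <- 30
  y <- rep(c("control", "patient"), each = n / 2)
  x <- cbind(info = ifelse(y == "patient", 1, -1) + rnorm(n, 0, 0.1),
             junk = rnorm(n))
  expect_equal(rfe_rank(x, y)[1], "info")
  expect_identical(rfe_rank(x, y), rfe_rank(x, y))
})

test_that("splits are half-sized, balanced, and rejections match the tail", {
  labels <- rep(c("control", "patient"), c(22, 21))
  for (s in 1:20) {
    sp <- make_split(labels, seed = s)
    expect_true(length(sp$train) %in% c(21, 22))
    expect_setequal(c(sp$train, sp$test), 1:43)
    shr <- mean(labels[sp$train] == "patient")
    expect_true(shr >= 0.4 && shr <= 0.6)
  }
  # rejection probability against the hypergeometric tail (10+10, train 10)
  lab2 <- rep(c("control", "patient"), each = 10)
  draws <- vapply(1:300, function(s) make_split(lab2, seed = s)$n_rejected,
                  numeric(1))
  p_rej_hat <- sum(draws) / (sum(draws) + length(draws))
  p_accept <- sum(stats::dhyper(4:6, 10, 10, 10))
  expect_lt(abs(p_rej_hat - (1 - p_accept)), 0.07)
})

test_that("bagged SVM is perfect on separable toys and reproducible", {
  fm <- toy_features(gap = 6, n_signal = 8)
  rep1 <- bagged_classification(fm, n_features = 2, n_iterations = 10,
                                condition = "actual", seed = 1)
  expect_equal(rep1$summary$test_selectivity, 1)
  expect_equal(rep1$summary$test_sensitivity, 1)
  expect_equal(rep1$summary$train_selectivity, 1)
  one_a <- bagged_classification(fm, n_features = 2, n_iterations = 1,
                                 condition = "actual", seed = 5)
  one_b <- bagged_classification(fm, n_features = 2, n_iterations = 1,
                                 condition = "actual", seed = 5)
  expect_identical(one_a$iterations, one_b$iterations)
})

test_that("label shuffling drives test performance to chance", {
  fm <- toy_features(gap = 6, n_signal = 8)
  pre <- bagged_classification(fm, n_features = 2, n_iterations = 150,
                               condition = "pre_shuffle", seed = 2)
  acc_pre <- mean(c(pre$summary$test_selectivity,
                    pre$summary$test_sensitivity))
  expect_true(acc_pre > 0.38 && acc_pre < 0.62)
  post <- bagged_classification(fm, n_features = 2, n_iterations = 150,
                                condition = "post_shuffle", seed = 3)
  acc_post <- mean(c(post$summary$test_selectivity,
                     post$summary$test_sensitivity))
  expect_true(acc_post > 0.38 && acc_post < 0.62)
  # post-shuffle training uses true labels: same as the actual condition
  act <- bagged_classification(fm, n_features = 2, n_iterations = 150,
                               condition = "actual", seed = 3)
  expect_equal(post$summary$train_selectivity,
               act$summary$train_selectivity)
  expect_equal(post$summary$train_sensitivity,
               act$summary$train_sensitivity)
})

test_that("accuracy grows with the feature count on structured cohorts", {
  fm <- toy_features(gap = 1.2, seed = 6, n_signal = 2)
  cv <- feature_count_curve(fm, k_values = c(1, 4), n_iterations = 60,
                            seed = 4)
  expect_equal(nrow(cv), 2)
  acc <- (cv$test_selectivity + cv$test_sensitivity) / 2
  expect_gte(acc[2], acc[1])
  single <- bagged_classification(fm, n_features = 4, n_iterations = 60,
                                  seed = derive_seed_test(4, 10004L))
  expect_equal(cv$k[2], 4)
  expect_equal(cv$test_selectivity[2], single$summary$test_selectivity)
  expect_equal(cv$test_sensitivity[2], single$summary$test_sensitivity)
})
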
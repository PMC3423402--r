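test_that("parcellation layout is bilateral, distinct and deterministic", {
  p <- make_parcellation(95, seed = 1)
  expect_equal(nrow(p), 95)
  expect_equal(sum(p$hemisphere == "bilateral"), 5)
  hp <- homologue_pairs(p)
  expect_equal(nrow(hp), 45)
  expect_equal(p$x[hp[, "left"]], -p$x[hp[, "right"]])
  expect_equal(p$y[hp[, "left"]], p$y[hp[, "right"]])
  expect_false(any(duplicated(p[, c("x", "y", "z")])))

  p4 <- make_parcellation(4, seed = 99)
  expect_equal(nrow(homologue_pairs(p4)), 2)

  expect_identical(make_parcellation(12, seed = 7),
                   make_parcellation(12, seed = 7))
  expect_error(make_parcellation(3), "at least 4")
})

test_that("group covariances are PSD with unit diagonal and planted contrast", {
  p <- make_parcellation(20, seed = 2)
  gt <- make_ground_truth(p, k_modules = 3, n_down = 3, n_up = 2, seed = 2)
  for (grp in c("control", "patient")) {
    cv <- build_group_covariance(p, gt, grp, seed = 3)
    expect_equal(diag(cv), rep(1, 20), ignore_attr = TRUE)
    expect_lt(max(abs(cv - t(cv))), 1e-12)
    expect_gt(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    same <- outer(gt$planted_partition, gt$planted_partition, "==")
    diag(same) <- NA
    expect_gt(mean(cv[same & !is.na(same)]),
              mean(cv[!same & !is.na(same)]))
  }
})

test_that("null effect gives identical group covariances", {
  p <- make_parcellation(16, seed = 4)
  gt <- make_ground_truth(p, k_modules = 2, n_down = 2, n_up = 1,
                          effect_size = 0, seed = 4)
  expect_identical(build_group_covariance(p, gt, "control", seed = 5),
                   build_group_covariance(p, gt, "patient", seed = 5))
})

test_that("true participation shifts monotonically with the planted effect", {
  p <- make_parcellation(24, seed = 6)
  for (es in c(0.15, 0.35, 0.6)) {
    gt <- make_ground_truth(p, k_modules = 3, n_down = 3, n_up = 2,
                            effect_size = es, seed = 6)
    cc <- build_group_covariance(p, gt, "control", seed = 7)
    cp <- build_group_covariance(p, gt, "patient", seed = 7)
    tc <- true_participation(cc, p, gt$planted_partition)
    tp <- true_participation(cp, p, gt$planted_partition)
    expect_true(all(tp[gt$affected_down] < tc[gt$affected_down]),
                label = sprintf("down nodes drop at effect %.2f", es))
    expect_true(all(tp[gt$affected_up] > tc[gt$affected_up]),
                label = sprintf("up nodes rise at effect %.2f", es))
  }
})

test_that("simulated series converge to the target correlation", {
  p <- make_parcellation(6, seed = 8)
  gt <- make_ground_truth(p, k_modules = 2, n_down = 1, n_up = 1, seed = 8)
  cv <- build_group_covariance(p, gt, "control", seed = 9)
  s <- simulate_subject(cv, n_timepoints = 50000, seed = 10)
  expect_lt(max(abs(stats::cor(s$data) - cv)), 0.03)
})

test_that("identity covariance yields near-independent columns", {
  n <- 20; tt <- 500
  s <- simulate_subject(diag(n), n_timepoints = tt, seed = 11)
  r <- stats::cor(s$data)
  frac <- mean(abs(r[upper.tri(r)]) > 1.96 / sqrt(tt))
  expect_lt(frac, 0.12)  # nominal 5% plus binomial slack over 190 pairs
})

test_that("subject simulation is bit-reproducible and validates input", {
  cv <- diag(4)
  expect_identical(simulate_subject(cv, 50, seed = 3)$data,
                   simulate_subject(cv, 50, seed = 3)$data)
  expect_error(simulate_subject(cv, 1, seed = 3), "at least 2")
})

test_that("cohort defaults match the study conditions", {
  co <- simulate_cohort(seed = 1)
  expect_length(co$subjects, 43)
  expect_equal(table(co$manifest$group),
               table(c(rep("control", 22), rep("patient", 21))))
  expect_equal(dim(co$subjects[[1]]$data), c(483, 95))
  expect_equal(co$subjects[[1]]$tr_seconds, 1.25)
  expect_equal(length(unique(co$ground_truth$planted_partition)), 5)
  expect_length(co$ground_truth$affected_down, 20)
  expect_length(co$ground_truth$affected_up, 9)
  expect_length(intersect(co$ground_truth$affected_down,
                          co$ground_truth$affected_up), 0)
})

test_that("cohort generation is reproducible and rejects bad configs", {
  a <- tiny_cohort(seed = 5)
  b <- tiny_cohort(seed = 5)
  expect_identical(a$subjects[[3]]$data, b$subjects[[3]]$data)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_error(simulate_cohort(n_control = 1, n_patient = 5),
               class = "brainmod_invalid_config")
  p <- make_parcellation(10, seed = 1)
  expect_error(
    make_ground_truth(p, k_modules = 2, affected_down = c(1, 2),
                      affected_up = c(2, 3), seed = 1),
    class = "brainmod_invalid_config")
})

test_that("cohort round-trips through disk and is byte-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co <- tiny_cohort(seed = 9, n_control = 3, n_patient = 3, n_regions = 10,
                    n_timepoints = 40, n_down = 2, n_up = 1)
  write_cohort(co, d1)
  simulate_cohort(n_control = 3, n_patient = 3, n_regions = 10,
                  n_timepoints = 40, k_modules = 3, n_down = 2, n_up = 1,
                  effect_size = 0.35, seed = 9, dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  back <- read_cohort(d1)
  expect_length(back$subjects, 6)
  expect_equal(back$subjects[[1]]$data, co$subjects[[1]]$data,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$ground_truth$planted_partition,
               co$ground_truth$planted_partition)
})
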
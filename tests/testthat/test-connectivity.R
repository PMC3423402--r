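test_that("pairwise correlation handles exact and hand-computed cases", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(-1, -2, -3),
             d = c(1, 3, 2))
  r <- compute_correlation(x)
  expect_equal(attr(r, "stage"), "raw")
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], 0.5)  # centred dot product: 1/2
  expect_equal(diag(unclass(r)), rep(1, 4), ignore_attr = TRUE)
})

test_that("zero-variance regions are reported by name", {
  x <- cbind(good = rnorm(10), flat = rep(2, 10))
  expect_error(compute_correlation(x), "flat",
               class = "brainmod_degenerate_series")
})

test_that("distance trend recovers exact and constant models", {
  p <- make_parcellation(12, seed = 3)
  d <- parcellation_distances(p)
  r <- 0.5 - 0.1 * log(d)
  diag(r) <- 1
  conn <- structure(r, class = c("connectivity_matrix", "matrix"),
                    stage = "raw", subject_id = "toy")
  m <- fit_distance_trend(conn, p)
  expect_equal(m$intercept, 0.5, tolerance = 1e-10)
  expect_equal(m$slope, -0.1, tolerance = 1e-10)
  expect_equal(m$residual_sd, 0, tolerance = 1e-8)
  expect_equal(m$n_pairs, 66)

  rc <- matrix(0.3, 12, 12); diag(rc) <- 1
  connc <- structure(rc, class = class(conn), stage = "raw",
                     subject_id = "toy")
  mc <- fit_distance_trend(connc, p)
  expect_equal(mc$slope, 0, tolerance = 1e-12)
  expect_equal(mc$intercept, 0.3, tolerance = 1e-12)
})

test_that("trend coefficients match the closed-form normal equations", {
  p <- make_parcellation(14, seed = 4)
  d <- parcellation_distances(p)
  set.seed(21)
  noise <- matrix(rnorm(14 * 14, 0, 0.1), 14, 14)
  noise <- (noise + t(noise)) / 2
  r <- 0.4 - 0.06 * log(d) + noise
  diag(r) <- 1
  conn <- structure(r, class = c("connectivity_matrix", "matrix"),
                    stage = "raw", subject_id = "toy")
  m <- fit_distance_trend(conn, p)
  ut <- upper.tri(d)
  X <- cbind(1, log(d[ut]))
  beta <- solve(t(X) %*% X, t(X) %*% r[ut])
  expect_equal(m$intercept, beta[1], tolerance = 1e-10)
  expect_equal(m$slope, beta[2], tolerance = 1e-10)
})

test_that("distance penalty residualises, symmetrises and is idempotent", {
  p <- make_parcellation(10, seed = 5)
  co <- tiny_cohort(seed = 5, n_control = 2, n_patient = 2, n_regions = 10,
                    n_timepoints = 60, n_down = 1, n_up = 1)
  conn <- compute_correlation(co$subjects[[1]])
  m <- fit_distance_trend(conn, co$parcellation)
  pen <- apply_distance_penalty(conn, m, co$parcellation)
  expect_equal(attr(pen, "stage"), "penalized")
  expect_equal(diag(unclass(pen)), rep(0, 10), ignore_attr = TRUE)
  expect_lt(max(abs(pen - t(pen))), 1e-12)
  # OLS residual property: zero mean over pairs
  expect_lt(abs(mean(pen[upper.tri(pen)])), 1e-12)
  # idempotence: refitting the penalized matrix finds a null trend
  m2 <- fit_distance_trend(pen, co$parcellation)
  expect_lt(abs(m2$slope), 1e-10)
  expect_lt(abs(m2$intercept), 1e-10)
  # exact-model input leaves all-zero residuals
  d <- parcellation_distances(co$parcellation)
  rexact <- 0.5 - 0.1 * log(d); diag(rexact) <- 1
  ce <- structure(rexact, class = class(conn), stage = "raw",
                  subject_id = "toy")
  pe <- apply_distance_penalty(ce, fit_distance_trend(ce, co$parcellation),
                               co$parcellation)
  expect_lt(max(abs(pe[upper.tri(pe)])), 1e-10)
})

test_that("penalty preserves ranking of equidistant pairs", {
  p <- make_parcellation(8, seed = 6)
  d <- parcellation_distances(p)
  co <- tiny_cohort(seed = 6, n_control = 2, n_patient = 2, n_regions = 8,
                    n_timepoints = 50, n_down = 1, n_up = 1)
  conn <- compute_correlation(co$subjects[[1]])
  pen <- apply_distance_penalty(conn, fit_distance_trend(conn, p), p)
  # homologue pairs are mirrored, so several pairs share distances; more
  # generally any two pairs at (near-)equal distance keep their order
  ut <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[ut]
  for (i in seq_len(nrow(ut) - 1)) {
    close <- which(abs(dv - dv[i]) < 1e-9)
    for (j in close[close > i]) {
      expect_equal(sign(conn[ut[i, , drop = FALSE]] -
                          conn[ut[j, , drop = FALSE]]),
                   sign(pen[ut[i, , drop = FALSE]] -
                          pen[ut[j, , drop = FALSE]]))
    }
  }
})

test_that("residual-error comparison behaves at the null and under shifts", {
  mk <- function(sds) lapply(sds, function(s)
    structure(list(intercept = 0, slope = 0, residual_sd = s, n_pairs = 10),
              class = "distance_model"))
  same <- compare_residual_errors(mk(c(0.1, 0.12, 0.14)),
                                  mk(c(0.1, 0.12, 0.14)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- compare_residual_errors(mk(c(0.10, 0.11, 0.12, 0.13)),
                                     mk(c(0.40, 0.41, 0.42, 0.43)))
  expect_lt(shifted$p_value, 0.01)
  expect_error(compare_residual_errors(mk(0.1), mk(c(0.1, 0.2))),
               class = "brainmod_insufficient_data")
})

test_that("null cohorts give uniform residual-comparison p-values", {
  ps <- vapply(1:60, function(s) {
    co <- simulate_cohort(n_control = 4, n_patient = 4, n_regions = 10,
                          n_timepoints = 60, k_modules = 2, n_down = 0,
                          n_up = 0, effect_size = 0, seed = 4000 + s)
    prep <- lapply(co$subjects, compute_correlation)
    models <- lapply(prep, fit_distance_trend,
                     parcellation = co$parcellation)
    compare_residual_errors(models[1:4], models[5:8])$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
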
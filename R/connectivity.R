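#' Pairwise Pearson correlation matrix of an ROI time series
#'
#' @param ts A `roi_ts` object (from [simulate_subject()] or
#'   [read_timeseries()]) or a plain T x N matrix.
#' @param subject_id Identifier attached to the result (taken from `ts` when
#'   available).
#'
#' @return A `connectivity_matrix`: symmetric N x N matrix of zero-lag
#'   Pearson correlations, unit diagonal, `stage = "raw"`.
#' @export
compute_correlation <- function(ts, subject_id = NULL) {
  x <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  if (is.null(subject_id)) {
    subject_id <- if (inherits(ts, "roi_ts")) ts$subject_id else "subject"
  }
  if (nrow(x) < 3) abort("at least 3 time points are required.")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    abort(sprintf("zero-variance region(s): %s",
                  paste(bad, collapse = ", ")),
          class = "brainmod_degenerate_series")
  }
  r <- stats::cor(x)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(r, class = c("connectivity_matrix", "matrix"),
            stage = "raw", subject_id = subject_id)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, stage = %s, subject = %s\n",
              nrow(x), ncol(x), attr(x, "stage"), attr(x, "subject_id")))
  invisible(x)
}

conn_weights <- function(conn) {
  w <- unclass(conn)
  attributes(w) <- attributes(w)[c("dim", "dimnames")]
  w
}

#' Fit the distance-dependent background trend of a correlation matrix
#'
#' Inter-regional resting-state correlations decay roughly logarithmically
#' with anatomical distance, a spatially non-specific background that masks
#' specific long-range coupling. This fits, per subject, ordinary least
#' squares of the raw correlations on log centroid distance over all
#' unordered region pairs.
#'
#' @param conn A raw-stage `connectivity_matrix`.
#' @param parcellation Parcellation supplying centroid distances.
#' @return A `distance_model`: list with `intercept`, `slope` (per log-mm),
#'   `residual_sd`, `n_pairs`.
#' @export
fit_distance_trend <- function(conn, parcellation) {
  check_symmetric(unclass(conn), arg = "conn")
  d <- parcellation_distances(parcellation)
  if (nrow(d) != nrow(conn)) abort("parcellation does not match matrix.")
  ut <- upper.tri(d)
  if (any(d[ut] <= 0)) abort("all pairwise distances must be positive.")
  ld <- log(d[ut])
  r <- conn_weights(conn)[ut]
  vx <- stats::var(ld)
  if (vx < 1e-14) {
    abort("all pairwise distances are equal; trend fit is singular.",
          class = "brainmod_singular_fit")
  }
  slope <- stats::cov(ld, r) / vx
  intercept <- mean(r) - slope * mean(ld)
  resid <- r - (intercept + slope * ld)
  structure(
    list(intercept = intercept, slope = slope,
         residual_sd = stats::sd(resid), n_pairs = length(r)),
    class = "distance_model"
  )
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf(
    "<distance_model> r = %.4f %+.4f * log(d); residual sd %.4f (%d pairs)\n",
    x$intercept, x$slope, x$residual_sd, x$n_pairs))
  invisible(x)
}

#' Remove the distance trend from a raw correlation matrix
#'
#' Subtracts the fitted `intercept + slope * log(d)` from every off-diagonal
#' entry, emphasising correlations that are strong relative to their spatial
#' proximity (homotopic and other long-range coupling). The diagonal is set
#' to zero and the result is marked `stage = "penalized"`.
#'
#' @param conn A raw-stage `connectivity_matrix`.
#' @param model The subject's [fit_distance_trend()] model.
#' @param parcellation Parcellation supplying the same distances.
#' @return A penalized-stage `connectivity_matrix` (signed, zero diagonal).
#' @export
apply_distance_penalty <- function(conn, model, parcellation) {
  d <- parcellation_distances(parcellation)
  if (nrow(d) != nrow(conn)) {
    abort("parcellation does not match matrix.", class = "brainmod_shape")
  }
  w <- conn_weights(conn)
  fit <- model$intercept + model$slope * log(pmax(d, 1e-12))
  out <- w - fit
  diag(out) <- 0
  out <- (out + t(out)) / 2
  structure(out, class = c("connectivity_matrix", "matrix"),
            stage = "penalized", subject_id = attr(conn, "subject_id"))
}

#' Compare distance-fit residual errors between groups
#'
#' Welch two-sample t-test on subject-wise residual standard deviations of
#' the distance-trend fits; used to verify that the distance adjustment
#' behaves comparably in the two groups.
#'
#' @param models_a,models_b Lists of `distance_model` objects, one group
#'   each.
#' @return A tibble with `statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `df`.
#' @export
compare_residual_errors <- function(models_a, models_b) {
  sa <- vapply(models_a, function(m) m$residual_sd, numeric(1))
  sb <- vapply(models_b, function(m) m$residual_sd, numeric(1))
  if (length(sa) < 2 || length(sb) < 2) {
    abort("at least 2 subjects per group are required.",
          class = "brainmod_insufficient_data")
  }
  ht <- welch_t(sa, sb)
  tibble::tibble(statistic = ht$statistic, p_value = ht$p_value,
                 mean_a = mean(sa), mean_b = mean(sb), df = ht$df)
}

# Welch t with the degenerate conventions used across the package:
# zero standard error and equal means -> t = 0, p = 1.
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  se <- sqrt(va + vb)
  diff <- mean(a) - mean(b)
  if (se == 0) {
    if (diff == 0) return(list(statistic = 0, p_value = 1, df = NA_real_))
    return(list(statistic = sign(diff) * Inf, p_value = 0, df = NA_real_))
  }
  tt <- diff / se
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(statistic = tt, p_value = 2 * stats::pt(-abs(tt), df), df = df)
}
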
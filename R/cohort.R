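#' Plant a ground-truth community structure and group effect
#'
#' Builds the "truth" object a synthetic cohort is generated from: a planted
#' module assignment (bilateral, i.e. homologue pairs share a module) and two
#' disjoint sets of affected nodes whose participation is shifted in the
#' patient group — `affected_down` nodes concentrate their connectivity
#' within their own module (participation decreases), `affected_up` nodes
#' spread it across modules (participation increases).
#'
#' @param parcellation A [make_parcellation()] tibble.
#' @param k_modules Number of planted modules (default 5).
#' @param n_down,n_up Number of affected nodes per direction (defaults 20
#'   and 9).
#' @param effect_size Fraction in \[0, 1\] of the affected nodes'
#'   cross-module (respectively within-module) covariance that is
#'   reallocated (default 0.35).
#' @param seed Integer seed.
#' @param connector_link Named numeric `c(prob, lo, hi)`: a cross-module
#'   pair (i, j) receives a specific link with probability
#'   `prob * connector_i * connector_j`, with strength uniform on
#'   `[lo, hi]`.
#' @param affected_down,affected_up Optional explicit node index vectors;
#'   must be disjoint.
#'
#' @return A list of class `ground_truth` with elements `planted_partition`
#'   (integer module per node), `affected_down`, `affected_up` (node
#'   indices), `effect_size`, `connector` (per-node connector propensity)
#'   and `links` (the symmetric cross-module link-strength matrix shared by
#'   both groups).
#' @export
make_ground_truth <- function(parcellation, k_modules = 5, n_down = 20,
                              n_up = 9, effect_size = 0.35, seed = 1,
                              connector_link = c(prob = 0.35, lo = 0.35,
                                                 hi = 0.55),
                              affected_down = NULL, affected_up = NULL) {
  n <- nrow(parcellation)
  k_modules <- as.integer(k_modules)
  if (effect_size < 0 || effect_size > 1) {
    abort("`effect_size` must lie in [0, 1].")
  }
  if (k_modules < 1L || k_modules > n) abort("invalid `k_modules`.")
  with_seed(derive_seed(seed, 101L), {
    pairs <- homologue_pairs(parcellation)
    midline <- which(parcellation$hemisphere == "bilateral")
    assignment <- integer(n)
    # Pairs assigned to modules as evenly as possible, bilaterally.
    if (nrow(pairs) > 0L) {
      mods <- sample(rep_len(seq_len(k_modules), nrow(pairs)))
      assignment[pairs[, "left"]] <- mods
      assignment[pairs[, "right"]] <- mods
    }
    if (length(midline) > 0L) {
      assignment[midline] <- sample(rep_len(seq_len(k_modules),
                                            length(midline)))
    }
    # Connector propensity: right-skewed, so most nodes are embedded in
    # their module while a minority carry strong cross-module coupling
    # (hub-like). Specific cross-module links are drawn from it: pair
    # (i, j) of different modules receives a link with probability
    # prob * c_i * c_j and strength uniform on [lo, hi]. The realised
    # links give nodes their nonzero participation.
    connector <- stats::rbeta(n, 1.5, 3)
    links <- matrix(0, n, n)
    cross <- upper.tri(links) & outer(assignment, assignment, "!=")
    pl <- pmin(connector_link[["prob"]] * (connector %o% connector), 1)
    links[cross] <- stats::rbinom(sum(cross), 1, pl[cross]) *
      stats::runif(sum(cross), connector_link[["lo"]],
                   connector_link[["hi"]])
    links <- links + t(links)
    link_mass <- rowSums(links)
    if (is.null(affected_down) && is.null(affected_up)) {
      # Nodes losing participation need realised cross-module links to
      # lose; nodes gaining participation start embedded in their module.
      has_links <- which(link_mass >= 0.3)
      if (length(has_links) < n_down) {
        has_links <- order(link_mass, decreasing = TRUE)[seq_len(n_down)]
      }
      affected_down <- has_links[sample.int(length(has_links), n_down)]
      embedded <- setdiff(which(link_mass < 0.3), affected_down)
      if (length(embedded) < n_up) {
        embedded <- setdiff(order(link_mass), affected_down)[seq_len(n_up)]
      }
      affected_up <- embedded[sample.int(length(embedded), n_up)]
    } else if (is.null(affected_down) || is.null(affected_up)) {
      have <- c(affected_down, affected_up)
      pick <- sample(setdiff(seq_len(n), have),
                     if (is.null(affected_down)) n_down else n_up)
      if (is.null(affected_down)) affected_down <- pick else
        affected_up <- pick
    }
    if (length(intersect(affected_down, affected_up)) > 0L) {
      abort("`affected_down` and `affected_up` must be disjoint.",
            class = "brainmod_invalid_config")
    }
    structure(
      list(planted_partition = assignment,
           affected_down = sort(as.integer(affected_down)),
           affected_up = sort(as.integer(affected_up)),
           effect_size = effect_size,
           connector = connector,
           links = links),
      class = "ground_truth"
    )
  })
}

#' Population covariance (correlation) matrix for one group
#'
#' Constructs the group-level population correlation matrix a synthetic
#' subject's ROI time series are drawn from. The baseline inter-regional
#' correlation decays with centroid distance as `a + b * log(d)` (clipped to
#' \[-0.9, 0.9\]), emulating the spatially non-specific background trend seen
#' in functional connectivity; a planted block structure adds
#' `module_contrast["within"]` to same-module pairs and
#' `module_contrast["between"]` to cross-module pairs; a small symmetric
#' jitter (`noise_sd`, drawn from `seed` and therefore identical across
#' groups) adds structural idiosyncrasy. For `group = "patient"`, each
#' affected node has a fraction `effect_size` of its cross-module
#' (`affected_down`) or within-module (`affected_up`) covariance reallocated
#' to the other side, shifting its true participation. The result is
#' repaired to the nearest positive semidefinite matrix by eigenvalue
#' clipping and rescaled to unit diagonal.
#'
#' @param parcellation A [make_parcellation()] tibble.
#' @param ground_truth A [make_ground_truth()] object.
#' @param group `"control"` or `"patient"`.
#' @param background Length-2 numeric `c(a, b)`: intercept and slope (per
#'   log-mm) of the distance trend. Defaults `c(0.55, -0.08)`.
#' @param noise_sd Standard deviation of the shared structural jitter.
#' @param module_contrast Length-2 numeric `c(within, between)` correlation
#'   offsets for the planted blocks.
#' @param connector_link Named numeric `c(prob, lo, hi)`: a cross-module
#'   pair (i, j) receives a specific link with probability
#'   `prob * connector_i * connector_j`, with strength uniform on
#'   `[lo, hi]`.
#' @param seed Seed for the link skeleton and jitter; use the same seed for
#'   both groups.
#'
#' @return N x N positive semidefinite correlation matrix with unit
#'   diagonal.
#' @export
build_group_covariance <- function(parcellation, ground_truth,
                                   group = c("control", "patient"),
                                   background = c(a = 0.55, b = -0.08),
                                   noise_sd = 0.05,
                                   module_contrast = c(within = 0.20,
                                                       between = -0.15),
                                   connector_link = c(prob = 0.35,
                                                      lo = 0.35,
                                                      hi = 0.55),
                                   seed = 1) {
  group <- match.arg(group)
  n <- nrow(parcellation)
  es <- ground_truth$effect_size
  if (es < 0 || es > 1) abort("`effect_size` must lie in [0, 1].")
  d <- parcellation_distances(parcellation)
  r <- background[[1]] + background[[2]] * log(pmax(d, 1e-6))
  r <- pmin(pmax(r, -0.9), 0.9)
  mod <- ground_truth$planted_partition
  same <- outer(mod, mod, "==")
  # Cross-module coupling is heterogeneous: connector-leaning node pairs
  # carry sparse specific links as strong as within-module edges (hub-like
  # long-range coupling), which is what gives nodes a nonzero participation
  # on the thresholded graph. Link placement and strength are drawn from
  # `seed`, so both groups share the same structural skeleton.
  r <- r + ifelse(same, module_contrast[[1]], module_contrast[[2]])
  link <- ground_truth$links
  if (is.null(link)) {
    con <- ground_truth$connector %||% rep(0, n)
    link <- with_seed(derive_seed(seed, 203L), {
      pl <- pmin(connector_link[["prob"]] * (con %o% con), 1)
      lk <- matrix(0, n, n)
      ut <- upper.tri(r) & !same
      lk[ut] <- stats::rbinom(sum(ut), 1, pl[ut]) *
        stats::runif(sum(ut), connector_link[["lo"]],
                     connector_link[["hi"]])
      lk + t(lk)
    })
  }
  jit <- with_seed(derive_seed(seed, 202L), {
    j <- matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    (j + t(j)) / 2
  })
  r <- r + link + jit
  diag(r) <- 1

  if (group == "patient" && es > 0) {
    base <- r
    affected <- c(ground_truth$affected_down, ground_truth$affected_up)
    for (i in affected) {
      down <- i %in% ground_truth$affected_down
      inside <- which(mod == mod[i] & seq_len(n) != i)
      outside <- which(mod != mod[i])
      # Mass moves only along edges to unaffected partners, so one node's
      # planted shift cannot cancel another's.
      outside <- setdiff(outside, affected)
      inside <- setdiff(inside, affected)
      from <- if (down) outside else inside
      to <- if (down) inside else outside
      # Reallocate a fraction `es` of the node's positive covariance mass
      # from one side of the module boundary to the other. The gained mass
      # concentrates on the node's few strongest partners on the receiving
      # side: recruited coupling attaches to specific regions rather than
      # diffusing evenly (and a diffuse gain would vanish at thresholding).
      from_pos <- pmax(base[i, from], 0)
      to_pos <- pmax(base[i, to], 0)
      keep_top <- order(to_pos, decreasing = TRUE)[seq_len(min(2L,
                                                    length(to_pos)))]
      to_top <- numeric(length(to_pos))
      to_top[keep_top] <- to_pos[keep_top]
      take <- es * sum(from_pos)
      if (take <= 0 || sum(to_top) <= 0) next
      r[i, from] <- r[i, from] - es * from_pos
      r[i, to] <- r[i, to] + take * to_top / sum(to_top)
    }
    r <- (r + t(r)) / 2
  }
  r[r > 0.98] <- 0.98
  r[r < -0.98] <- -0.98
  diag(r) <- 1
  repair_psd(r)
}

# Nearest-PSD repair: clip eigenvalues at `floor`, rescale to unit diagonal.
repair_psd <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (any(!is.finite(e$values))) {
    abort("covariance could not be repaired (non-finite eigenvalues).",
          class = "brainmod_degenerate_covariance")
  }
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  dg <- diag(out)
  if (any(dg <= 0) || any(!is.finite(out))) {
    abort("covariance could not be repaired to positive semidefinite.",
          class = "brainmod_degenerate_covariance")
  }
  out <- out / sqrt(dg %o% dg)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  out
}

#' Simulate one subject's ROI time series
#'
#' Rows are independent zero-mean multivariate normal draws with the given
#' covariance. Temporal autocorrelation is deliberately not modelled: every
#' downstream stage consumes only zero-lag correlations.
#'
#' @param cov Positive semidefinite covariance matrix.
#' @param n_timepoints Number of time points T (>= 2); default 483.
#' @param seed Integer seed; draws are bit-reproducible.
#' @param subject_id,group,tr_seconds Metadata carried on the result.
#'
#' @return An object of class `roi_ts`: list with `subject_id`, `group`,
#'   `data` (T x N matrix, columns named by region) and `tr_seconds`.
#' @export
simulate_subject <- function(cov, n_timepoints = 483, seed = 1,
                             subject_id = "sub01", group = "control",
                             tr_seconds = 1.25) {
  if (n_timepoints < 2) abort("`n_timepoints` must be at least 2.")
  check_symmetric(cov, tol = 1e-6, arg = "cov")
  x <- with_seed(seed, MASS::mvrnorm(n_timepoints, mu = rep(0, nrow(cov)),
                                     Sigma = cov))
  colnames(x) <- colnames(cov)
  structure(list(subject_id = subject_id, group = group, data = x,
                 tr_seconds = tr_seconds),
            class = "roi_ts")
}

#' Simulate a two-group resting-state cohort
#'
#' Generates the full study-condition cohort: by default 22 control and 21
#' patient subjects, 95 regions, 483 time points at TR 1.25 s, 5 planted
#' bilateral modules, and a patient-group participation shift in 20
#' down-affected and 9 up-affected nodes.
#'
#' @param n_control,n_patient Subjects per group (>= 2 each).
#' @param n_regions,n_timepoints,tr_seconds Dimensions of each subject's
#'   series.
#' @param k_modules,n_down,n_up,effect_size Passed to
#'   [make_ground_truth()].
#' @param background,noise_sd,module_contrast,connector_link Generator
#'   parameters; see [make_ground_truth()] and [build_group_covariance()].
#' @param seed Root seed; per-subject seeds are derived from it.
#' @param affected_down,affected_up Optional explicit affected-node sets.
#' @param dir Optional output directory; when given, the cohort is written
#'   there via [write_cohort()].
#'
#' @return A list of class `cohort`: `subjects` (list of `roi_ts`),
#'   `parcellation`, `ground_truth`, `covariances` (per-group population
#'   matrices) and `manifest` (tibble: subject_id, group, path).
#' @export
#' @examples
#' co <- simulate_cohort(n_control = 3, n_patient = 3, n_regions = 12,
#'                       n_timepoints = 60, seed = 1)
#' co$manifest
simulate_cohort <- function(n_control = 22, n_patient = 21, n_regions = 95,
                            n_timepoints = 483, tr_seconds = 1.25,
                            k_modules = 5, n_down = 20, n_up = 9,
                            effect_size = 0.35,
                            background = c(a = 0.55, b = -0.08),
                            noise_sd = 0.05,
                            module_contrast = c(within = 0.20,
                                                between = -0.15),
                            connector_link = c(prob = 0.35, lo = 0.35,
                                               hi = 0.55),
                            seed = 1, affected_down = NULL,
                            affected_up = NULL, dir = NULL) {
  if (n_control < 2 || n_patient < 2) {
    abort("at least 2 subjects per group are required.",
          class = "brainmod_invalid_config")
  }
  parc <- make_parcellation(n_regions, seed = derive_seed(seed, 1L))
  gt <- make_ground_truth(parc, k_modules = k_modules, n_down = n_down,
                          n_up = n_up, effect_size = effect_size,
                          seed = derive_seed(seed, 2L),
                          connector_link = connector_link,
                          affected_down = affected_down,
                          affected_up = affected_up)
  covs <- list(
    control = build_group_covariance(parc, gt, "control",
                                     background = background,
                                     noise_sd = noise_sd,
                                     module_contrast = module_contrast,
                                     connector_link = connector_link,
                                     seed = derive_seed(seed, 3L)),
    patient = build_group_covariance(parc, gt, "patient",
                                     background = background,
                                     noise_sd = noise_sd,
                                     module_contrast = module_contrast,
                                     connector_link = connector_link,
                                     seed = derive_seed(seed, 3L))
  )
  groups <- c(rep("control", n_control), rep("patient", n_patient))
  ids <- sprintf("sub%03d", seq_along(groups))
  subjects <- purrr::map(seq_along(groups), function(i) {
    simulate_subject(covs[[groups[i]]], n_timepoints = n_timepoints,
                     seed = derive_seed(seed, 1000L + i),
                     subject_id = ids[i], group = groups[i],
                     tr_seconds = tr_seconds)
  })
  manifest <- tibble::tibble(
    subject_id = ids, group = groups,
    path = file.path("timeseries", paste0(ids, ".tsv"))
  )
  cohort <- structure(
    list(subjects = subjects, parcellation = parc, ground_truth = gt,
         covariances = covs, manifest = manifest, seed = seed),
    class = "cohort"
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects (%d control / %d patient), %d regions, T = %d\n",
    length(x$subjects), sum(x$manifest$group == "control"),
    sum(x$manifest$group == "patient"), nrow(x$parcellation),
    nrow(x$subjects[[1]]$data)))
  invisible(x)
}

#' True (population) participation of each node
#'
#' Computes the participation index analytically from a group's population
#' correlation matrix and the planted partition: the matrix is
#' distance-penalized exactly as in the pipeline and participation is taken
#' over the positive residual weights (no thresholding, so the value is a
#' smooth function of the covariance).
#'
#' @param cov Population correlation matrix.
#' @param parcellation Matching parcellation.
#' @param partition Integer module assignment.
#' @return Numeric vector of participation values in \[0, 1\].
#' @export
true_participation <- function(cov, parcellation, partition) {
  conn <- structure(cov, class = c("connectivity_matrix", "matrix"),
                    stage = "raw", subject_id = "population")
  model <- fit_distance_trend(conn, parcellation)
  pen <- apply_distance_penalty(conn, model, parcellation)
  w <- unclass(pen)
  attributes(w) <- attributes(w)[c("dim", "dimnames")]
  w[w < 0] <- 0
  pi_from_weights(w, partition)
}
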
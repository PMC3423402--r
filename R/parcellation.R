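#' Generate a bilateral brain parcellation layout
#'
#' Creates a synthetic parcellation emulating an anatomical atlas: homologue
#' left/right region pairs with mirrored x coordinates plus a small set of
#' midline (bilateral) regions straddling x = 0, as in atlases where the
#' cingulate subdivisions are merged across hemispheres. Centroids are in mm
#' within a roughly brain-sized bounding box.
#'
#' @param n_regions Total number of regions (>= 4). With the default 95 the
#'   layout is 45 homologue pairs plus 5 midline regions.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param n_midline Number of midline regions. Defaults to 0 for even
#'   `n_regions` and to 5 (or the smallest odd count that fits) for odd
#'   `n_regions`, so the remainder splits into left/right pairs.
#'
#' @return A tibble of class `parcellation` with columns `region`,
#'   `hemisphere` (`"left"`, `"right"`, `"bilateral"`), and centroid
#'   coordinates `x`, `y`, `z` in mm.
#' @export
#' @examples
#' p <- make_parcellation(10, seed = 1)
#' table(p$hemisphere)
make_parcellation <- function(n_regions = 95, seed = 1, n_midline = NULL) {
  if (!is.numeric(n_regions) || n_regions < 4) {
    abort("`n_regions` must be at least 4.")
  }
  n_regions <- as.integer(n_regions)
  if (is.null(n_midline)) {
    n_midline <- if (n_regions %% 2L == 0L) 0L else min(5L, n_regions - 4L)
    if ((n_regions - n_midline) %% 2L != 0L) n_midline <- 1L
  }
  n_midline <- as.integer(n_midline)
  if (n_midline < 0L || (n_regions - n_midline) %% 2L != 0L ||
      n_regions - n_midline < 0L) {
    abort("`n_midline` must leave an even number of lateralised regions.")
  }
  n_pairs <- (n_regions - n_midline) %/% 2L

  with_seed(seed, {
    # Lateral pairs: mirrored x, shared y/z; jitter keeps centroids distinct.
    px <- stats::runif(n_pairs, 15, 65)
    py <- stats::runif(n_pairs, -85, 60)
    pz <- stats::runif(n_pairs, -45, 70)
    mx <- rep(0, n_midline)
    my <- stats::runif(n_midline, -80, 55)
    mz <- stats::runif(n_midline, -30, 65)
    region <- character(0)
    hemisphere <- character(0)
    x <- y <- z <- numeric(0)
    if (n_pairs > 0L) {
      nm <- sprintf("Region%02d", seq_len(n_pairs))
      region <- c(paste0(nm, "_L"), paste0(nm, "_R"))
      hemisphere <- rep(c("left", "right"), each = n_pairs)
      x <- c(-px, px)
      y <- c(py, py)
      z <- c(pz, pz)
    }
    if (n_midline > 0L) {
      region <- c(region, sprintf("Midline%02d", seq_len(n_midline)))
      hemisphere <- c(hemisphere, rep("bilateral", n_midline))
      x <- c(x, mx)
      y <- c(y, my)
      z <- c(z, mz)
    }
    # Interleave so homologues sit next to each other (L, R, L, R, ...).
    ord <- if (n_pairs > 0L) {
      c(as.vector(rbind(seq_len(n_pairs), seq_len(n_pairs) + n_pairs)),
        if (n_midline > 0L) 2L * n_pairs + seq_len(n_midline))
    } else seq_len(n_midline)
    out <- tibble::tibble(
      region = region[ord], hemisphere = hemisphere[ord],
      x = x[ord], y = y[ord], z = z[ord]
    )
    class(out) <- c("parcellation", class(out))
    out
  })
}

#' Pairwise Euclidean centroid distances of a parcellation
#'
#' @param parcellation A [make_parcellation()] tibble (or any data frame with
#'   `x`, `y`, `z` columns).
#' @return A symmetric N x N matrix of distances in mm.
#' @export
parcellation_distances <- function(parcellation) {
  stopifnot(all(c("x", "y", "z") %in% names(parcellation)))
  d <- as.matrix(stats::dist(as.matrix(parcellation[, c("x", "y", "z")])))
  dimnames(d) <- list(parcellation$region, parcellation$region)
  d
}

#' Homologue index pairs of a parcellation
#'
#' @param parcellation A [make_parcellation()] tibble.
#' @return A two-column integer matrix; each row is the (left, right) index
#'   pair of one homologue.
#' @export
homologue_pairs <- function(parcellation) {
  base <- sub("_[LR]$", "", parcellation$region)
  left <- which(parcellation$hemisphere == "left")
  right <- match(paste0(base[left], "_R"), parcellation$region)
  cbind(left = left, right = right)
}
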
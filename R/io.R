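# Plain-text readers/writers for cohorts, matrices, partitions and reports.

#' Write a cohort to disk
#'
#' Writes `manifest.csv` (subject_id, group, path), `parcellation.csv`
#' (region, hemisphere, x, y, z), `ground_truth.json`, and one TSV per
#' subject (T rows x N columns, header = region names) under
#' `timeseries/`.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(tibble::as_tibble(cohort$parcellation),
                   file.path(dir, "parcellation.csv"))
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(planted_partition = gt$planted_partition,
         affected_down = gt$affected_down, affected_up = gt$affected_up,
         effect_size = gt$effect_size),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  for (s in cohort$subjects) {
    df <- tibble::as_tibble(s$data, .name_repair = "minimal")
    colnames(df) <- colnames(s$data)
    readr::write_tsv(df, file.path(dir, "timeseries",
                                   paste0(s$subject_id, ".tsv")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.csv`,
#'   `parcellation.csv` and the per-subject TSVs; `ground_truth.json` is
#'   attached when present.
#' @param tr_seconds Repetition time attached to the series.
#' @return A `cohort` object (without population covariances).
#' @export
read_cohort <- function(dir, tr_seconds = 1.25) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  parc <- readr::read_csv(file.path(dir, "parcellation.csv"),
                          show_col_types = FALSE)
  class(parc) <- c("parcellation", class(parc))
  subjects <- purrr::pmap(manifest, function(subject_id, group, path) {
    read_timeseries(file.path(dir, path), subject_id = subject_id,
                    group = group, tr_seconds = tr_seconds)
  })
  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt <- structure(
      list(planted_partition = as.integer(raw$planted_partition),
           affected_down = as.integer(raw$affected_down),
           affected_up = as.integer(raw$affected_up),
           effect_size = raw$effect_size),
      class = "ground_truth")
  }
  structure(list(subjects = subjects, parcellation = parc,
                 ground_truth = gt, covariances = NULL,
                 manifest = manifest, seed = NA_integer_),
            class = "cohort")
}

#' Read one subject's ROI time-series TSV
#'
#' @param path TSV with a region-name header row.
#' @param subject_id,group,tr_seconds Metadata for the returned object.
#' @return A `roi_ts` object.
#' @export
read_timeseries <- function(path, subject_id = basename(path),
                            group = "control", tr_seconds = 1.25) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  structure(list(subject_id = subject_id, group = group,
                 data = as.matrix(df), tr_seconds = tr_seconds),
            class = "roi_ts")
}

#' Write a connectivity matrix as TSV with region names
#'
#' @param conn A `connectivity_matrix`.
#' @param path Output path.
#' @export
write_connectivity <- function(conn, path) {
  w <- conn_weights(conn)
  df <- tibble::as_tibble(w, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(region = rownames(w) %||%
                                          as.character(seq_len(nrow(w)))),
                         df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a sparse graph as a weighted edge list (TSV)
#'
#' @param g A `sparse_graph`.
#' @param path Output path; columns `node_i`, `node_j`, `weight`.
#' @export
write_edge_list <- function(g, path) {
  w <- g$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  nm <- colnames(w) %||% as.character(seq_len(nrow(w)))
  readr::write_tsv(tibble::tibble(node_i = nm[idx[, 1]],
                                  node_j = nm[idx[, 2]],
                                  weight = w[idx]), path)
  invisible(path)
}

#' Write a partition as CSV (node, region, module)
#'
#' @param partition A `brain_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(generics::tidy(partition), path)
  invisible(path)
}
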
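#' Read and write package file formats
#'
#' Tabular artifacts are comma-separated with a fixed header schema; dense
#' similarity matrices are tab-separated with region ids as header row and
#' column; morphometry tables are long-format tab-separated with columns
#' `subject_id`, `region_id`, `vertex_index`, `value`.
#'
#' @param mat A similarity matrix with region-id dimnames.
#' @param path File path.
#' @return Readers return tibbles (or a matrix); writers return the path
#'   invisibly.
#' @name mbn_io
NULL

#' @rdname mbn_io
#' @export
write_similarity_matrix <- function(mat, path) {
  df <- as.data.frame(unclass(mat))
  names(df) <- rownames(mat)
  df <- cbind(region_id = rownames(mat), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname mbn_io
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$region_id)
  class(mat) <- c("mbn_similarity_matrix", class(mat))
  mat
}

#' @rdname mbn_io
#' @param edges An edge table (`subject_id`, `region_a`, `region_b`,
#'   `similarity`).
#' @export
write_edge_list <- function(edges, path) {
  readr::write_csv(edges, path)
  invisible(path)
}

#' Read a long-format morphometry table
#'
#' Validates structure on the way in: required columns, numeric finite
#' values, and (when a scheme is given) no unknown regions. Malformed rows
#' are reported with their file line numbers.
#'
#' @param path Tab-separated file with columns `subject_id`, `region_id`,
#'   `vertex_index`, `value`.
#' @param scheme Optional parcellation scheme to check region ids against.
#' @return A tibble.
#' @export
read_morphometry <- function(path, scheme = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           region_id = readr::col_integer(),
                           vertex_index = readr::col_integer(),
                           value = readr::col_double()
                         ))
  required <- c("subject_id", "region_id", "vertex_index", "value")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("`", path, "` is missing column(s): ",
                 paste(missing, collapse = ", "), "."),
          class = "mbn_validation_error")
  }
  bad <- which(!is.finite(tbl$value) | is.na(tbl$region_id) |
                 is.na(tbl$subject_id))
  if (!is.null(scheme)) {
    scheme <- validate_scheme(scheme)
    bad <- union(bad, which(!tbl$region_id %in% scheme$region_id))
  }
  if (length(bad) > 0) {
    # +1 for the header line
    lines <- head(sort(bad) + 1L, 20)
    abort(paste0("Malformed row(s) in `", path, "` at line(s): ",
                 paste(lines, collapse = ", "),
                 if (length(bad) > 20) sprintf(" (and %d more)",
                                               length(bad) - 20) else "",
                 ". Values must be finite numbers and regions known."),
          class = "mbn_validation_error")
  }
  tbl
}

#' Read a cohort metadata table
#'
#' @param path CSV with columns `subject_id`, `group`, `age`, `sex` and any
#'   clinical columns.
#' @return A tibble with `group` and `sex` as factors.
#' @export
read_cohort_metadata <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("`", path, "` is missing column(s): ",
                 paste(missing, collapse = ", "), "."),
          class = "mbn_validation_error")
  }
  if (!is.numeric(tbl$age) || anyNA(tbl$age)) {
    abort(paste0("`", path, "`: column `age` must be numeric with no missing values."),
          class = "mbn_validation_error")
  }
  tbl$group <- factor(tbl$group, levels = unique(tbl$group))
  tbl$sex <- factor(tbl$sex)
  tbl
}

#' Write a simulated cohort to disk
#'
#' Writes the long-format morphometry table (TSV), the metadata table (CSV)
#' and the ground-truth record (JSON) into a directory.
#'
#' @param cohort An `mbn_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$morphometry, file.path(dir, "morphometry.tsv"))
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  gt <- cohort$ground_truth
  gt$affected_pairs <- as.data.frame(gt$affected_pairs)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Extract per-region vertex values from a gray-matter volume and atlas
#'
#' Optional ingestion path for real data: given a (modulated) gray-matter
#' feature volume and an integer atlas label volume on the same grid (NIfTI,
#' read via the RNifti package), returns the voxel values of each labelled
#' region as the region's vertex values.
#'
#' @param gm_path Path to the gray-matter feature volume.
#' @param atlas_path Path to the integer label volume (0 = background).
#' @param subject_id Subject identifier attached to the rows.
#' @return A tibble with columns `subject_id`, `region_id`, `vertex_index`,
#'   `value`.
#' @export
region_values_from_volumes <- function(gm_path, atlas_path,
                                       subject_id = "S001") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Package `RNifti` is required to read NIfTI volumes.")
  }
  gm <- as.vector(RNifti::readNifti(gm_path))
  labels <- as.vector(RNifti::readNifti(atlas_path))
  if (length(gm) != length(labels)) {
    abort("Feature and atlas volumes must share the same grid.",
          class = "mbn_validation_error")
  }
  keep <- labels > 0
  vals <- split(gm[keep], labels[keep])
  tibble::tibble(
    subject_id = subject_id,
    region_id = rep(as.integer(names(vals)), lengths(vals)),
    vertex_index = unlist(lapply(lengths(vals), seq_len), use.names = FALSE),
    value = unlist(vals, use.names = FALSE)
  )
}
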
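#' Parcellation schemes
#'
#' A parcellation scheme is the node definition of a morphological brain
#' network: an ordered table of region ids, names and hemisphere tags.
#' `default_scheme()` returns a 116-region scheme structured like the AAL-116
#' atlas (45 regions per cerebral hemisphere plus 26 cerebellar/vermis
#' regions); `toy_scheme()` returns a small generic scheme for simulation and
#' testing. Any data frame with columns `region_id`, `region_name` and
#' `hemisphere` passes [validate_scheme()] and can be used throughout the
#' package, so alternative atlases (e.g. a 112-region Harvard-Oxford style
#' parcellation) are supported by supplying their region table.
#'
#' @param n_regions Number of regions in the toy scheme (>= 3).
#' @return A tibble with columns `region_id` (integer), `region_name`
#'   (character) and `hemisphere` (one of `"left"`, `"right"`,
#'   `"cerebellar"`, `"midline"`).
#' @examples
#' default_scheme()
#' toy_scheme(6)
#' @export
default_scheme <- function() {
  tibble::tibble(
    region_id = 1:116,
    region_name = c(
      sprintf("cortical_%02d_L", 1:45),
      sprintf("cortical_%02d_R", 1:45),
      sprintf("cerebellum_%02d", 1:26)
    ),
    hemisphere = c(rep("left", 45), rep("right", 45), rep("cerebellar", 26))
  )
}

#' @rdname default_scheme
#' @export
toy_scheme <- function(n_regions) {
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 3) {
    abort("`n_regions` must be an integer >= 3.")
  }
  tibble::tibble(
    region_id = seq_len(n_regions),
    region_name = sprintf("region_%03d", seq_len(n_regions)),
    hemisphere = rep(c("left", "right"), length.out = n_regions)
  )
}

#' Validate a parcellation scheme
#'
#' Checks the invariants every scheme must satisfy: the three required
#' columns, unique integer region ids, and at least three regions.
#'
#' @param scheme A data frame describing the parcellation.
#' @return The scheme as a tibble, invisibly usable downstream.
#' @export
validate_scheme <- function(scheme) {
  if (!is.data.frame(scheme)) {
    abort("`scheme` must be a data frame.")
  }
  required <- c("region_id", "region_name", "hemisphere")
  missing <- setdiff(required, names(scheme))
  if (length(missing) > 0) {
    abort(paste0("`scheme` is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  ids <- scheme$region_id
  if (anyNA(ids) || any(ids != as.integer(ids))) {
    abort("`scheme$region_id` must be non-missing integers.")
  }
  if (anyDuplicated(ids) > 0) {
    abort("`scheme$region_id` must be unique.")
  }
  if (nrow(scheme) < 3) {
    abort("A parcellation scheme needs at least 3 regions.")
  }
  tibble::as_tibble(scheme)
}

n_region_pairs <- function(n_regions) {
  n_regions * (n_regions - 1L) / 2L
}
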
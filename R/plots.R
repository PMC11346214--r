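#' Plot metric profiles across the sparsity grid
#'
#' Group mean curves (with standard-deviation ribbons when metadata is
#' supplied) of global topological metrics as a function of sparsity.
#'
#' @param object An `mbn_metrics` table from [compute_metrics()].
#' @param metadata Optional cohort metadata with `subject_id` and `group`;
#'   when given, curves are drawn per group.
#' @param metrics Which global metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbn_metrics <- function(object, metadata = NULL,
                                 metrics = c("C_p", "L_p", "E_glob",
                                             "E_loc"),
                                 ...) {
  d <- dplyr::filter(object, .data$level == "global",
                     .data$metric %in% metrics)
  if (!is.null(metadata)) {
    d <- dplyr::left_join(d, metadata[, c("subject_id", "group")],
                          by = "subject_id")
  } else {
    d$group <- "all"
  }
  s <- d |>
    dplyr::group_by(.data$group, .data$metric, .data$sparsity) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(.data$sparsity, .data$mean,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = "metric value",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot the NBS permutation null against observed component sizes
#'
#' Histogram of the maximal-component-size null distribution with vertical
#' lines at the observed component sizes.
#'
#' @param object An `mbn_nbs` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbn_nbs <- function(object, ...) {
  null_d <- tibble::tibble(size = object$null_max_size)
  p <- ggplot2::ggplot(null_d, ggplot2::aes(.data$size)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5,
                            fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "maximal component size (edges) under permutation",
                  y = "permutations") +
    ggplot2::theme_minimal()
  if (nrow(object$components) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$components,
      ggplot2::aes(xintercept = .data$n_edges),
      colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot covariate-adjusted group differences
#'
#' Nodal metrics are shown as -log10 FDR-adjusted p-values per region,
#' split by metric family and coloured by direction; global metrics as a
#' labelled dot plot.
#'
#' @param object An `mbn_group_test` from [compare_groups()].
#' @param alpha Significance level drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbn_group_test <- function(object, alpha = 0.05, ...) {
  d <- dplyr::mutate(object,
                     label = ifelse(.data$level == "global", .data$metric,
                                    as.character(.data$region_id)))
  ggplot2::ggplot(d, ggplot2::aes(.data$label, -log10(.data$p_fdr),
                                  colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p[FDR]),
                  colour = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Heatmap of one subject's similarity matrix
#'
#' @param object An `mbn_similarity_matrix` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbn_similarity_matrix <- function(object, ...) {
  ids <- rownames(object)
  d <- expand.grid(region_a = ids, region_b = ids,
                   stringsAsFactors = FALSE)
  d$similarity <- as.vector(unclass(object))
  d$region_a <- factor(d$region_a, levels = ids)
  d$region_b <- factor(d$region_b, levels = rev(ids))
  ggplot2::ggplot(d, ggplot2::aes(.data$region_a, .data$region_b,
                                  fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
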
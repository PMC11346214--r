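#' Primary screen for suprathreshold connections
#'
#' First stage of network-based statistics. Two screening modes are
#' available:
#'
#' * `"node-restricted"` (default): run the covariate-adjusted group ANCOVA
#'   on each region's nodal AUC profiles (degree, efficiency, betweenness)
#'   and keep nodes significant at raw `p < alpha` in at least one of the
#'   three; the suprathreshold connections are all region pairs whose
#'   endpoints are screened-in (`edge_rule = "both"`) or that touch at least
#'   one screened-in node (`edge_rule = "any"`).
#' * `"edge-wise"`: run the ANCOVA on every edge's similarity values and
#'   keep edges with raw `p < alpha` (the canonical NBS screen).
#'
#' @param metadata Cohort metadata (`subject_id`, group, covariates).
#' @param auc An `mbn_auc` table with nodal metrics (node-restricted mode).
#' @param similarity An `mbn_similarity` edge table (edge-wise mode).
#' @param mode Screening mode.
#' @param alpha Primary (uncorrected) screening level in (0, 1).
#' @param edge_rule How node-restricted screening turns nodes into edges.
#' @param group,covariates Column names in `metadata`.
#' @return A tibble of suprathreshold edges (`region_a`, `region_b`) with
#'   attributes `screened_nodes`, `mode`, and `alpha`.
#' @export
primary_screen <- function(metadata, auc = NULL, similarity = NULL,
                           mode = c("node-restricted", "edge-wise"),
                           alpha = 0.05,
                           edge_rule = c("both", "any"),
                           group = "group", covariates = c("age", "sex")) {
  mode <- match.arg(mode)
  edge_rule <- match.arg(edge_rule)
  check_alpha(alpha)
  prep <- screen_inputs(metadata, auc, similarity, mode, group, covariates)
  p <- ancova_f_matrix(prep$Y, prep$g$indicator, prep$Z)$p_value
  screened_edges(p, prep, mode, alpha, edge_rule)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).",
          class = "mbn_parameter_error")
  }
}

# Assemble the response matrix, design pieces and pair bookkeeping shared by
# the observed screen and the permutation loop.
screen_inputs <- function(metadata, auc, similarity, mode, group,
                          covariates) {
  md <- dplyr::arrange(metadata, .data$subject_id)
  g <- group_indicator(md[[group]])
  Z <- covariate_matrix(md, covariates)
  check_design_rank(g$indicator, Z, n = nrow(md))

  if (mode == "node-restricted") {
    if (is.null(auc)) abort("Node-restricted screening needs `auc`.")
    nodal <- auc[auc$level == "nodal", ]
    if (nrow(nodal) == 0) abort("`auc` contains no nodal metrics.")
    wide <- nodal |>
      dplyr::mutate(key = paste(.data$metric, .data$region_id, sep = "|")) |>
      dplyr::select("subject_id", "key", "auc") |>
      tidyr::pivot_wider(names_from = "key", values_from = "auc") |>
      dplyr::arrange(.data$subject_id)
    if (!identical(wide$subject_id, md$subject_id)) {
      abort("`auc` and `metadata` must cover the same subjects.",
            class = "mbn_validation_error")
    }
    keys <- strsplit(setdiff(names(wide), "subject_id"), "|", fixed = TRUE)
    regions <- sort(unique(nodal$region_id))
    list(Y = as.matrix(wide[, -1, drop = FALSE]), g = g, Z = Z, md = md,
         col_region = vapply(keys, function(k) as.integer(k[2]), 1L),
         regions = regions, pairs = NULL)
  } else {
    if (is.null(similarity)) abort("Edge-wise screening needs `similarity`.")
    wide <- similarity |>
      dplyr::mutate(key = paste(.data$region_a, .data$region_b, sep = "|")) |>
      dplyr::select("subject_id", "key", "similarity") |>
      tidyr::pivot_wider(names_from = "key", values_from = "similarity") |>
      dplyr::arrange(.data$subject_id)
    if (!identical(wide$subject_id, md$subject_id)) {
      abort("`similarity` and `metadata` must cover the same subjects.",
            class = "mbn_validation_error")
    }
    keys <- strsplit(setdiff(names(wide), "subject_id"), "|", fixed = TRUE)
    pairs <- tibble::tibble(
      region_a = vapply(keys, function(k) as.integer(k[1]), 1L),
      region_b = vapply(keys, function(k) as.integer(k[2]), 1L)
    )
    regions <- sort(unique(c(pairs$region_a, pairs$region_b)))
    list(Y = as.matrix(wide[, -1, drop = FALSE]), g = g, Z = Z, md = md,
         col_region = NULL, regions = regions, pairs = pairs)
  }
}

# Turn per-column screen p-values into a suprathreshold edge table.
screened_edges <- function(p, prep, mode, alpha, edge_rule) {
  if (mode == "node-restricted") {
    hit <- tapply(p < alpha, prep$col_region, any)
    nodes <- sort(as.integer(names(hit)[hit]))
    edges <- node_rule_edges(nodes, prep$regions, edge_rule)
  } else {
    nodes <- integer(0)
    edges <- prep$pairs[p < alpha, , drop = FALSE]
  }
  attr(edges, "screened_nodes") <- nodes
  attr(edges, "mode") <- mode
  attr(edges, "alpha") <- alpha
  edges
}

# Edge universe is complete (every region pair carries a similarity), so the
# node rules enumerate pairs directly.
node_rule_edges <- function(nodes, regions, edge_rule) {
  empty <- tibble::tibble(region_a = integer(0), region_b = integer(0))
  if (length(nodes) == 0) return(empty)
  if (edge_rule == "both") {
    if (length(nodes) < 2) return(empty)
    m <- t(combn(nodes, 2))
  } else {
    others <- setdiff(regions, nodes)
    within <- if (length(nodes) >= 2) t(combn(nodes, 2)) else
      matrix(integer(0), ncol = 2)
    touch <- as.matrix(expand.grid(region_a = nodes, region_b = others))
    m <- rbind(within, cbind(pmin(touch[, 1], touch[, 2]),
                             pmax(touch[, 1], touch[, 2])))
  }
  tibble::tibble(region_a = as.integer(m[, 1]),
                 region_b = as.integer(m[, 2])) |>
    dplyr::arrange(.data$region_a, .data$region_b)
}

#' Connected components of a suprathreshold edge set
#'
#' Partitions an edge set into maximal connected components and reports each
#' component's node and edge counts. Component size, as used by the
#' permutation test, is the edge count.
#'
#' @param edges A data frame with columns `region_a`, `region_b`.
#' @return A list of class `mbn_components` with elements `edges` (the input
#'   plus a `component_id` column) and `components` (tibble: `component_id`,
#'   `n_nodes`, `n_edges`), ordered by decreasing edge count.
#' @examples
#' connected_components(data.frame(region_a = c(1, 2, 7),
#'                                 region_b = c(2, 3, 8)))$components
#' @export
connected_components <- function(edges) {
  if (nrow(edges) == 0) {
    return(structure(list(
      edges = tibble::tibble(region_a = integer(0), region_b = integer(0),
                             component_id = integer(0)),
      components = tibble::tibble(component_id = integer(0),
                                  n_nodes = integer(0), n_edges = integer(0))
    ), class = "mbn_components"))
  }
  el <- cbind(as.character(edges$region_a), as.character(edges$region_b))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  edge_comp <- unname(memb[el[, 1]])
  # relabel components by decreasing edge count (ties: first appearance)
  counts <- table(edge_comp)
  new_id <- rank(-as.integer(counts), ties.method = "first")
  names(new_id) <- names(counts)
  edge_comp <- as.integer(new_id[as.character(edge_comp)])
  node_comp <- as.integer(new_id[as.character(memb)])
  out_edges <- tibble::tibble(region_a = edges$region_a,
                              region_b = edges$region_b,
                              component_id = edge_comp)
  components <- tibble::tibble(
    component_id = sort(unique(edge_comp)),
    n_nodes = as.integer(tabulate(node_comp)[sort(unique(edge_comp))]),
    n_edges = as.integer(tabulate(edge_comp)[sort(unique(edge_comp))])
  )
  structure(list(edges = out_edges, components = components),
            class = "mbn_components")
}

#' @export
print.mbn_components <- function(x, ...) {
  cat(sprintf("<mbn_components> %d component(s)\n", nrow(x$components)))
  print(x$components)
  invisible(x)
}

#' Network-based statistics with a permutation null
#'
#' Component-level inference on group differences in connectivity: the
#' primary screen of [primary_screen()] defines suprathreshold connections,
#' their connected components are extracted, and each observed component's
#' size (edge count) is referred to the null distribution of the *maximal*
#' component size over group-label permutations (covariates stay attached to
#' their subjects and remain in the permuted fits). Per-component
#' \eqn{p = (b + 1) / (n_{perm} + 1)} where \eqn{b} counts permutations whose
#' maximal component size reaches the observed size; Benjamini-Hochberg FDR
#' is additionally applied across the observed components, and both adjusted
#' values are reported.
#'
#' @inheritParams primary_screen
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed; the result is fully determined by the data,
#'   configuration and seed.
#' @return An object of class `mbn_nbs`: a list with `components` (tibble:
#'   `component_id`, `n_nodes`, `n_edges`, `p_perm`, `p_fdr`), `edges`
#'   (per-edge component membership), `screened_nodes`, `null_max_size`
#'   (integer vector of length `n_perm`), and `config`.
#' @export
nbs <- function(metadata, auc = NULL, similarity = NULL,
                mode = c("node-restricted", "edge-wise"),
                alpha = 0.05, n_perm = 5000L,
                edge_rule = c("both", "any"),
                group = "group", covariates = c("age", "sex"),
                seed = 1L) {
  mode <- match.arg(mode)
  edge_rule <- match.arg(edge_rule)
  check_alpha(alpha)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100) {
    warn("Fewer than 100 permutations; p-values will be coarse.")
  }
  prep <- screen_inputs(metadata, auc, similarity, mode, group, covariates)
  if (min(table(prep$g$indicator)) < 5) {
    warn("A group has fewer than 5 subjects; the permutation null may be degenerate.")
  }

  obs_p <- ancova_f_matrix(prep$Y, prep$g$indicator, prep$Z)$p_value
  obs_edges <- screened_edges(obs_p, prep, mode, alpha, edge_rule)
  obs_comp <- connected_components(obs_edges)

  null_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      g_perm <- sample(prep$g$indicator)
      p <- ancova_f_matrix(prep$Y, g_perm, prep$Z)$p_value
      max_component_size(p, prep, mode, alpha, edge_rule)
    }, integer(1))
  })

  components <- obs_comp$components
  if (nrow(components) > 0) {
    components$p_perm <- vapply(components$n_edges, function(sz) {
      (1 + sum(null_max >= sz)) / (n_perm + 1)
    }, numeric(1))
    components$p_fdr <- bh_fdr(components$p_perm)
  } else {
    components$p_perm <- numeric(0)
    components$p_fdr <- numeric(0)
  }

  structure(
    list(
      components = components,
      edges = obs_comp$edges,
      screened_nodes = attr(obs_edges, "screened_nodes"),
      null_max_size = null_max,
      config = list(mode = mode, alpha = alpha, n_perm = n_perm,
                    edge_rule = edge_rule, seed = as.integer(seed),
                    group_levels = prep$g$levels,
                    n_subjects = nrow(prep$md))
    ),
    class = "mbn_nbs"
  )
}

# Maximal component edge count for one permutation. With a complete edge
# universe the node rules yield closed forms; the edge-wise screen falls back
# to explicit component extraction.
max_component_size <- function(p, prep, mode, alpha, edge_rule) {
  if (mode == "node-restricted") {
    hit <- tapply(p < alpha, prep$col_region, any)
    k <- sum(hit)
    R <- length(prep$regions)
    if (edge_rule == "both") {
      return(as.integer(k * (k - 1L) / 2L))
    }
    if (k == 0) return(0L)
    total <- R * (R - 1L) / 2L
    return(as.integer(total - (R - k) * (R - k - 1L) / 2L))
  }
  edges <- prep$pairs[p < alpha, , drop = FALSE]
  if (nrow(edges) == 0) return(0L)
  comp <- connected_components(edges)
  max(comp$components$n_edges)
}

#' @export
print.mbn_nbs <- function(x, ...) {
  cat(sprintf("<mbn_nbs> mode = %s, alpha = %g, %d permutations\n",
              x$config$mode, x$config$alpha, x$config$n_perm))
  if (nrow(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    print(x$components)
  }
  invisible(x)
}

#' @describeIn nbs Tidy per-component results.
#' @param x An `mbn_nbs` object.
#' @param ... Unused.
#' @export
tidy.mbn_nbs <- function(x, ...) {
  x$components
}

#' @describeIn nbs One-row summary of the NBS run.
#' @export
glance.mbn_nbs <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    alpha = x$config$alpha,
    n_perm = x$config$n_perm,
    n_components = nrow(x$components),
    n_significant = sum(x$components$p_perm < 0.05),
    max_observed_size = if (nrow(x$components)) max(x$components$n_edges)
    else 0L,
    null_max_q95 = stats::quantile(x$null_max_size, 0.95, names = FALSE)
  )
}
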
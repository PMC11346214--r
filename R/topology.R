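#' Sparsity grid for network thresholding
#'
#' Sparsity is the fraction of all possible edges retained when a similarity
#' matrix is binarised. The default analysis grid is 0.05 to 0.40 in steps of
#' 0.05 (8 levels), covering the range in which individual morphological
#' networks are sparse yet estimable.
#'
#' @param from,to,by Grid limits and step.
#' @return A strictly increasing numeric vector of sparsity levels in (0, 1).
#' @export
sparsity_grid <- function(from = 0.05, to = 0.40, by = 0.05) {
  s <- seq(from, to, by = by)
  validate_sparsity_grid(s)
}

validate_sparsity_grid <- function(s) {
  if (length(s) < 1 || any(!is.finite(s)) || any(s <= 0 | s >= 1) ||
      is.unsorted(s, strictly = TRUE)) {
    abort("Sparsity levels must be strictly increasing and inside (0, 1).",
          class = "mbn_parameter_error")
  }
  s
}

#' Configuration of the degree-preserving random reference set
#'
#' Normalised clustering (\eqn{\gamma}) and path length (\eqn{\lambda}) are
#' ratios against the mean of degree-matched random graphs obtained by
#' double-edge-swap rewiring. Each reference performs
#' `swaps_per_edge * |E|` swap attempts, preserving the degree sequence
#' exactly.
#'
#' @param n_ref Number of reference graphs (0 disables \eqn{\gamma},
#'   \eqn{\lambda}, \eqn{\sigma}).
#' @param swaps_per_edge Swap attempts per edge of the source graph.
#' @param seed Seed for the rewiring stream.
#' @return A list of class `mbn_reference_config`.
#' @export
reference_config <- function(n_ref = 100L, swaps_per_edge = 10L, seed = 1L) {
  n_ref <- as.integer(n_ref)
  if (is.na(n_ref) || n_ref < 0) {
    abort("`n_ref` must be a nonnegative integer.",
          class = "mbn_parameter_error")
  }
  structure(list(n_ref = n_ref, swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "mbn_reference_config")
}

#' Threshold a similarity matrix at a sparsity level
#'
#' Retains exactly `round(S * P)` strongest edges (P = number of off-diagonal
#' unordered pairs) and binarises them. Ties are broken deterministically by
#' descending similarity, then ascending `(region_a, region_b)`; with a fixed
#' matrix this makes edge sets nested across increasing sparsity levels.
#'
#' @param mat A symmetric similarity matrix with region-id dimnames.
#' @param sparsity A single sparsity level in (0, 1).
#' @return A binary symmetric adjacency matrix (zero diagonal) with the same
#'   dimnames.
#' @export
threshold_by_sparsity <- function(mat, sparsity) {
  if (!is.numeric(sparsity) || length(sparsity) != 1 ||
      !is.finite(sparsity) || sparsity <= 0 || sparsity >= 1) {
    abort("`sparsity` must be a single value in (0, 1).",
          class = "mbn_parameter_error")
  }
  eo <- edge_order(mat)
  k <- round(sparsity * eo$P)
  keep <- eo$ord[seq_len(k)]
  adj <- matrix(0, eo$R, eo$R, dimnames = dimnames(mat))
  adj[cbind(eo$ia[keep], eo$ib[keep])] <- 1
  adj[cbind(eo$ib[keep], eo$ia[keep])] <- 1
  adj
}

# Deterministic edge ranking shared by all thresholding: descending
# similarity, ties broken by ascending (region_a, region_b) position.
edge_order <- function(mat) {
  mat <- unclass(mat)
  R <- nrow(mat)
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  sims <- mat[idx]
  list(R = R, P = nrow(idx), ia = idx[, 1], ib = idx[, 2], sims = sims,
       ord = order(-sims, idx[, 1], idx[, 2]))
}

# Canonical graph constructor: edges sorted by (a, b). A fixed edge order
# makes the degree-preserving rewiring stream reproducible no matter how the
# graph was assembled.
edges_to_graph <- function(ea, eb, R) {
  o <- order(ea, eb)
  igraph::make_graph(as.vector(rbind(ea[o], eb[o])), n = R,
                     directed = FALSE)
}

graph_from_adj <- function(adj) {
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  edges_to_graph(idx[, 1], idx[, 2], nrow(adj))
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    abort("`adj` must be a square adjacency matrix.")
  }
  if (nrow(adj) < 3) {
    abort("Graph metrics need at least 3 nodes.",
          class = "mbn_parameter_error")
  }
  if (any(adj != t(adj)) || any(diag(adj) != 0)) {
    abort("`adj` must be symmetric with a zero diagonal.")
  }
  invisible(adj)
}

# Mean inverse shortest-path length over ordered off-diagonal pairs;
# unreachable pairs contribute 0.
efficiency_from_dist <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Global topological metrics of a binary graph
#'
#' Computes the seven global profiles of a thresholded network: clustering
#' coefficient \eqn{C_p} (mean local clustering, nodes of degree < 2
#' contribute 0), characteristic path length \eqn{L_p} (mean shortest path
#' over connected node pairs; the number of unreachable pairs is reported),
#' global efficiency \eqn{E_{glob}} (mean inverse shortest-path length over
#' all pairs), local efficiency \eqn{E_{loc}} (mean over nodes of the global
#' efficiency of each node's neighbour-induced subgraph), and the normalised
#' ratios \eqn{\gamma = C_p / C_p^{rand}}, \eqn{\lambda = L_p / L_p^{rand}}
#' and the small-world index \eqn{\sigma = \gamma / \lambda}, where the
#' random baselines are means over degree-preserving rewired references.
#'
#' @param adj Binary symmetric adjacency matrix (zero diagonal, >= 3 nodes).
#' @param null_config A [reference_config()]; with `n_ref = 0` the normalised
#'   metrics are `NA`.
#' @param references Optional explicit list of reference adjacency matrices
#'   (used instead of generating rewired references).
#' @return A one-row tibble with columns `C_p`, `L_p`, `gamma`, `lambda`,
#'   `sigma`, `E_glob`, `E_loc`, and `n_unreachable_pairs`.
#' @export
global_metrics <- function(adj, null_config = reference_config(),
                           references = NULL) {
  check_adjacency(adj)
  g <- graph_from_adj(adj)
  d <- igraph::distances(g)
  off <- d[upper.tri(d)]
  finite_off <- off[is.finite(off)]
  if (length(finite_off) == 0) {
    abort("Graph is fully disconnected; characteristic path length is undefined.",
          class = "mbn_disconnected_graph")
  }
  cp <- mean_local_clustering(g)
  lp <- mean(finite_off)
  eglob <- efficiency_from_dist(d)
  eloc <- local_efficiency(adj, g)
  n_unreach <- 2L * sum(!is.finite(off))

  gamma <- lambda <- sigma <- NA_real_
  if (is.null(references) && !is.null(null_config) && null_config$n_ref > 0) {
    references <- reference_graphs(adj, null_config)
  }
  if (!is.null(references) && length(references) > 0) {
    ref_stats <- vapply(references, function(r) {
      rg <- if (igraph::is_igraph(r)) r else graph_from_adj(r)
      rd <- igraph::distances(rg)
      roff <- rd[upper.tri(rd)]
      roff <- roff[is.finite(roff)]
      c(C = mean_local_clustering(rg),
        L = if (length(roff)) mean(roff) else NA_real_)
    }, numeric(2))
    c_rand <- mean(ref_stats["C", ])
    l_rand <- mean(ref_stats["L", ])
    if (!is.na(c_rand) && c_rand > 0) gamma <- cp / c_rand else {
      warn("Reference clustering is zero; gamma undefined.")
    }
    if (!is.na(l_rand) && l_rand > 0) lambda <- lp / l_rand
    sigma <- gamma / lambda
  }

  tibble::tibble(C_p = cp, L_p = lp, gamma = gamma, lambda = lambda,
                 sigma = sigma, E_glob = eglob, E_loc = eloc,
                 n_unreachable_pairs = n_unreach)
}

mean_local_clustering <- function(g) {
  tr <- igraph::transitivity(g, type = "local", isolates = "zero")
  tr[is.nan(tr)] <- 0 # degree-1 nodes
  mean(tr)
}

local_efficiency <- function(adj, g = graph_from_adj(adj)) {
  vals <- vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    efficiency_from_dist(igraph::distances(sub))
  }, numeric(1))
  mean(vals)
}

#' Degree-preserving random reference graphs
#'
#' Generates rewired copies of a graph by repeated double-edge swaps, keeping
#' every node's degree fixed. Used as the random baseline for the normalised
#' clustering and path-length ratios.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param null_config A [reference_config()].
#' @return A list of adjacency matrices with identical degree sequences.
#' @export
reference_graphs <- function(adj, null_config = reference_config()) {
  check_adjacency(adj)
  g <- graph_from_adj(adj)
  n_swap <- null_config$swaps_per_edge * igraph::ecount(g)
  withr::with_seed(null_config$seed, {
    lapply(seq_len(null_config$n_ref), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swap))
      m <- as.matrix(igraph::as_adjacency_matrix(r))
      dimnames(m) <- dimnames(adj)
      m
    })
  })
}

#' Nodal topological metrics of a binary graph
#'
#' Per-node degree \eqn{D_i} (incident edges), nodal efficiency \eqn{E_i}
#' (mean of \eqn{1/d(i,j)} over all other nodes, unreachable nodes
#' contributing 0), and betweenness centrality \eqn{B_i} (number of shortest
#' paths between other node pairs passing through \eqn{i}, fractionally
#' counted over path multiplicities, unnormalised).
#'
#' @param adj Binary symmetric adjacency matrix with region-id dimnames.
#' @return A tibble with columns `region_id`, `degree`, `efficiency`,
#'   `betweenness`.
#' @export
nodal_metrics <- function(adj) {
  check_adjacency(adj)
  g <- graph_from_adj(adj)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  ids <- rownames(adj) %||% as.character(seq_len(nrow(adj)))
  tibble::tibble(
    region_id = as.integer(ids),
    degree = as.integer(rowSums(adj != 0)),
    efficiency = rowSums(inv) / (nrow(adj) - 1),
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  )
}

#' Compute topological metric profiles across the sparsity grid
#'
#' Thresholds each subject's similarity network at every sparsity level and
#' computes the requested global and nodal metrics, returned as one tidy
#' table ready for [auc_summary()].
#'
#' @param similarity An `mbn_similarity` edge table from [build_networks()].
#' @param sparsity Sparsity grid (see [sparsity_grid()]).
#' @param null_config A [reference_config()] for the normalised global
#'   metrics; use `n_ref = 0` to skip them.
#' @param metrics Which families to compute: `"global"`, `"nodal"` or both.
#' @return A tibble of class `mbn_metrics` with columns `subject_id`,
#'   `sparsity`, `level` ("global"/"nodal"), `metric`, `region_id` (`NA` for
#'   global metrics) and `value`.
#' @export
compute_metrics <- function(similarity,
                            sparsity = sparsity_grid(),
                            null_config = reference_config(),
                            metrics = c("global", "nodal")) {
  validate_sparsity_grid(sparsity)
  metrics <- match.arg(metrics, c("global", "nodal"), several.ok = TRUE)
  do_global <- "global" %in% metrics
  do_nodal <- "nodal" %in% metrics
  with_refs <- do_global && !is.null(null_config) && null_config$n_ref > 0
  global_cols <- if (with_refs) {
    c("C_p", "L_p", "gamma", "lambda", "sigma", "E_glob", "E_loc")
  } else {
    c("C_p", "L_p", "E_glob", "E_loc")
  }
  subjects <- unique(similarity$subject_id)

  per_subject <- lapply(subjects, function(s) {
    mat <- similarity_matrix(similarity, s)
    eo <- edge_order(mat)
    R <- eo$R
    ids <- as.integer(rownames(mat))
    g_rows <- vector("list", length(sparsity))
    n_rows <- vector("list", length(sparsity))
    for (li in seq_along(sparsity)) {
      S <- sparsity[li]
      keep <- eo$ord[seq_len(round(S * eo$P))]
      ea <- eo$ia[keep]
      eb <- eo$ib[keep]
      g <- edges_to_graph(ea, eb, R)
      d <- igraph::distances(g)
      inv <- 1 / d
      diag(inv) <- 0
      inv[!is.finite(inv)] <- 0
      if (do_nodal) {
        n_rows[[li]] <- list(
          degree = tabulate(c(ea, eb), nbins = R),
          efficiency = rowSums(inv) / (R - 1),
          betweenness = igraph::betweenness(g)
        )
      }
      if (do_global) {
        fin <- d[upper.tri(d)]
        fin <- fin[is.finite(fin)]
        if (length(fin) == 0) {
          abort(sprintf(
            "Subject %s at sparsity %.2f is fully disconnected; path length undefined.",
            s, S), class = "mbn_disconnected_graph")
        }
        cp <- mean_local_clustering(g)
        lp <- mean(fin)
        eglob <- sum(inv) / (R * (R - 1))
        eloc <- local_efficiency_graph(g, ea, eb, R)
        vals <- c(C_p = cp, L_p = lp, E_glob = eglob, E_loc = eloc)
        if (with_refs) {
          rs <- reference_stats(g, null_config)
          gamma <- if (rs["C"] > 0) cp / rs["C"] else NA_real_
          lambda <- if (rs["L"] > 0) lp / rs["L"] else NA_real_
          vals <- c(C_p = cp, L_p = lp, gamma = gamma, lambda = lambda,
                    sigma = gamma / lambda, E_glob = eglob, E_loc = eloc)
        }
        g_rows[[li]] <- vals
      }
    }
    n_levels <- length(sparsity)
    out <- list()
    if (do_global) {
      s_col <- rep(sparsity, each = length(global_cols))
      m_col <- rep(global_cols, n_levels)
      out$global <- tibble::tibble(
        subject_id = s,
        sparsity = s_col,
        level = "global",
        metric = m_col,
        region_id = NA_integer_,
        value = as.numeric(unlist(g_rows))
      )
    }
    if (do_nodal) {
      s_col <- rep(sparsity, each = 3L * R)
      m_col <- rep(rep(c("degree", "efficiency", "betweenness"),
                       each = R), n_levels)
      r_col <- rep(rep(ids, 3L), n_levels)
      out$nodal <- tibble::tibble(
        subject_id = s,
        sparsity = s_col,
        level = "nodal",
        metric = m_col,
        region_id = r_col,
        value = as.numeric(unlist(lapply(n_rows, function(r) {
          c(r$degree, r$efficiency, r$betweenness)
        })))
      )
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(per_subject)
  attr(out, "sparsity") <- sparsity
  class(out) <- c("mbn_metrics", class(out))
  out
}

# Mean C and L over degree-preserving rewired references of one graph.
reference_stats <- function(g, null_config) {
  n_swap <- null_config$swaps_per_edge * igraph::ecount(g)
  withr::with_seed(null_config$seed, {
    stats <- vapply(seq_len(null_config$n_ref), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swap))
      rd <- igraph::distances(r)
      roff <- rd[upper.tri(rd)]
      roff <- roff[is.finite(roff)]
      c(C = mean_local_clustering(r),
        L = if (length(roff)) mean(roff) else NA_real_)
    }, numeric(2))
    c(C = mean(stats["C", ]), L = mean(stats["L", ]))
  })
}

# Local efficiency from an edge list without densifying the adjacency.
local_efficiency_graph <- function(g, ea, eb, R) {
  nb <- vector("list", R)
  for (k in seq_along(ea)) {
    nb[[ea[k]]] <- c(nb[[ea[k]]], eb[k])
    nb[[eb[k]]] <- c(nb[[eb[k]]], ea[k])
  }
  vals <- vapply(seq_len(R), function(i) {
    ni <- nb[[i]]
    if (length(ni) < 2) return(0)
    sub <- igraph::induced_subgraph(g, ni)
    efficiency_from_dist(igraph::distances(sub))
  }, numeric(1))
  mean(vals)
}

#' Trapezoidal area under a metric curve
#'
#' @param x Strictly increasing grid (sparsity levels).
#' @param y Metric values at the grid points (no missing values).
#' @return The trapezoidal integral of `y` over `x`.
#' @examples
#' auc_trapezoid(sparsity_grid(), rep(2, 8)) # 0.35 * 2
#' @export
auc_trapezoid <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2.")
  }
  if (anyNA(y) || any(!is.finite(y))) {
    abort("Metric values contain missing or non-finite entries; AUC is not imputed.",
          class = "mbn_missing_value")
  }
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Summarise metric profiles by area under the curve across sparsity
#'
#' Integrates each metric's profile over the sparsity grid with the
#' trapezoidal rule, yielding one threshold-independent scalar per subject
#' and metric (and per region for nodal metrics). Every grid level must be
#' present; missing levels raise an error rather than being imputed.
#'
#' @param metrics An `mbn_metrics` table from [compute_metrics()].
#' @param sparsity The grid used; defaults to the grid stored on `metrics`.
#' @return A tibble of class `mbn_auc` with columns `subject_id`, `level`,
#'   `metric`, `region_id` and `auc`.
#' @export
auc_summary <- function(metrics, sparsity = NULL) {
  sparsity <- sparsity %||% attr(metrics, "sparsity")
  if (is.null(sparsity)) {
    abort("Supply the sparsity grid (none stored on `metrics`).")
  }
  validate_sparsity_grid(sparsity)
  if (anyNA(metrics$value) || any(!is.finite(metrics$value))) {
    abort("Metric values contain missing or non-finite entries; AUC is not imputed.",
          class = "mbn_missing_value")
  }
  if (!all(metrics$sparsity %in% sparsity)) {
    abort("Metric table contains sparsity levels outside the grid.",
          class = "mbn_missing_value")
  }
  counts <- metrics |>
    dplyr::group_by(.data$subject_id, .data$level, .data$metric,
                    .data$region_id) |>
    dplyr::summarise(n_levels = dplyr::n_distinct(.data$sparsity),
                     .groups = "drop")
  if (any(counts$n_levels != length(sparsity))) {
    abort("Metric profile is missing sparsity levels; AUC is not imputed.",
          class = "mbn_missing_value")
  }
  out <- metrics |>
    dplyr::arrange(.data$sparsity) |>
    dplyr::group_by(.data$subject_id, .data$level, .data$metric,
                    .data$region_id) |>
    dplyr::summarise(auc = sum(diff(.data$sparsity) *
                                 (head(.data$value, -1) +
                                    .data$value[-1]) / 2),
                     .groups = "drop")
  class(out) <- c("mbn_auc", class(out))
  out
}
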
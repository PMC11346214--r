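test_that("thresholding retains exactly round(S * P) strongest edges", {
  co <- toy_cohort(n_per_group = 2, n_regions = 12, seed = 5)
  sim <- build_networks(co)
  mat <- similarity_matrix(sim, "S001")
  P <- choose(12, 2)
  for (S in sparsity_grid()) {
    adj <- threshold_by_sparsity(mat, S)
    expect_equal(sum(adj) / 2, round(S * P))
    expect_equal(adj, t(adj))
    expect_equal(diag(adj), setNames(rep(0, 12), 1:12))
  }
  expect_error(threshold_by_sparsity(mat, 0), class = "mbn_parameter_error")
  expect_error(threshold_by_sparsity(mat, 1), class = "mbn_parameter_error")
})

test_that("edge sets are nested across increasing sparsity", {
  co <- toy_cohort(n_per_group = 1, n_regions = 14, seed = 9)
  mat <- similarity_matrix(build_networks(co), "S001")
  prev <- NULL
  for (S in sparsity_grid()) {
    adj <- threshold_by_sparsity(mat, S)
    if (!is.null(prev)) expect_true(all(adj[prev == 1] == 1))
    prev <- adj
  }
})

test_that("a 4-node matrix at S = 0.5 keeps the 3 largest edges", {
  m <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  sims <- c(0.9, 0.5, 0.8, 0.4, 0.7, 0.6)
  m[upper.tri(m)] <- sims
  m <- m + t(m)
  adj <- threshold_by_sparsity(m, 0.5)
  # brute force: the 3 largest similarities
  keep <- which(upper.tri(m), arr.ind = TRUE)[order(-sims)[1:3], ]
  expect_equal(sum(adj) / 2, 3)
  expect_true(all(adj[keep] == 1))
})

test_that("near-full sparsity yields the complete graph", {
  co <- toy_cohort(n_per_group = 1, n_regions = 6, seed = 2)
  mat <- similarity_matrix(build_networks(co), "S001")
  adj <- threshold_by_sparsity(mat, 0.999)
  expect_equal(sum(adj), 6 * 5)
})

test_that("global metrics match closed forms on canonical graphs", {
  k5 <- global_metrics(adj_complete(5), null_config = NULL)
  expect_equal(k5$C_p, 1)
  expect_equal(k5$L_p, 1)
  expect_equal(k5$E_glob, 1)
  expect_equal(k5$E_loc, 1)

  p3 <- global_metrics(adj_path(3), null_config = NULL)
  expect_equal(p3$L_p, 4 / 3)
  expect_equal(p3$E_glob, 5 / 6)
  expect_equal(p3$C_p, 0)

  c4 <- global_metrics(adj_cycle(4), null_config = NULL)
  expect_equal(c4$L_p, 4 / 3)
  expect_equal(c4$E_glob, 5 / 6)
})

test_that("nodal metrics match closed forms on canonical graphs", {
  c4 <- nodal_metrics(adj_cycle(4))
  expect_equal(c4$degree, rep(2L, 4))
  star <- nodal_metrics(adj_star(3))
  expect_equal(star$betweenness[1], 3) # all leaf pairs route via the hub
  expect_equal(star$betweenness[-1], rep(0, 3))
  expect_equal(star$degree, c(3L, 1L, 1L, 1L))
  # isolated node: no finite paths, zero efficiency
  adj <- rbind(cbind(adj_path(3), 0), 0)
  dimnames(adj) <- list(1:4, 1:4)
  nm <- nodal_metrics(adj)
  expect_equal(nm$efficiency[4], 0)
  expect_equal(nm$degree[4], 0L)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    m <- sample(n:(choose(n, 2) - 1), 1)
    adj <- random_adjacency(n, m)
    d <- fw_distances(adj)
    if (!any(is.finite(d[upper.tri(d)]))) next
    gm <- global_metrics(adj, null_config = NULL)
    expect_equal(gm$C_p, mean(brute_clustering(adj)), tolerance = 1e-9)
    expect_equal(gm$L_p, brute_char_path_length(d), tolerance = 1e-9)
    expect_equal(gm$E_glob, brute_global_efficiency(d), tolerance = 1e-9)
    expect_equal(gm$E_loc, brute_local_efficiency(adj), tolerance = 1e-9)
    nm <- nodal_metrics(adj)
    expect_equal(nm$degree, as.integer(rowSums(adj)))
    expect_equal(nm$efficiency, brute_nodal_efficiency(d), tolerance = 1e-9)
    expect_equal(nm$betweenness, unname(brute_betweenness(adj)),
                 tolerance = 1e-9)
  }
})

test_that("normalised metrics are ratios against the reference means", {
  set.seed(5)
  adj <- random_adjacency(10, 20)
  refs <- reference_graphs(adj, reference_config(n_ref = 8, seed = 31))
  gm <- global_metrics(adj, references = refs)
  c_rand <- mean(vapply(refs, function(r) mean(brute_clustering(r)),
                        numeric(1)))
  l_rand <- mean(vapply(refs, function(r) {
    brute_char_path_length(fw_distances(r))
  }, numeric(1)))
  expect_equal(gm$gamma, gm$C_p / c_rand, tolerance = 1e-9)
  expect_equal(gm$lambda, gm$L_p / l_rand, tolerance = 1e-9)
  expect_equal(gm$sigma, gm$gamma / gm$lambda, tolerance = 1e-12)
})

test_that("rewired references preserve the degree sequence exactly", {
  set.seed(8)
  adj <- random_adjacency(12, 24)
  refs <- reference_graphs(adj, reference_config(n_ref = 10, seed = 4))
  for (r in refs) {
    expect_equal(rowSums(r), rowSums(adj))
    expect_equal(r, t(r))
    expect_equal(diag(r), diag(adj))
  }
  # seeded: regeneration is identical
  refs2 <- reference_graphs(adj, reference_config(n_ref = 10, seed = 4))
  expect_identical(refs, refs2)
})

test_that("randomising an already-random graph leaves gamma and lambda near 1", {
  set.seed(123)
  adj <- random_adjacency(30, 140)
  gm <- global_metrics(adj, reference_config(n_ref = 30, seed = 11))
  expect_gt(gm$gamma, 0.7)
  expect_lt(gm$gamma, 1.3)
  expect_gt(gm$lambda, 0.9)
  expect_lt(gm$lambda, 1.1)
})

test_that("a lattice-like ring graph is small-world against its references", {
  # ring lattice: high clustering, long paths; sigma = gamma / lambda > 1
  n <- 24
  adj <- matrix(0, n, n, dimnames = list(1:n, 1:n))
  for (i in seq_len(n)) {
    for (k in 1:2) {
      j <- ((i + k - 1) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1
    }
  }
  gm <- global_metrics(adj, reference_config(n_ref = 20, seed = 3))
  expect_gt(gm$sigma, 1)
})

test_that("degenerate graphs are rejected", {
  expect_error(global_metrics(matrix(0, 2, 2)),
               class = "mbn_parameter_error")
  empty <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  expect_error(global_metrics(empty, null_config = NULL),
               class = "mbn_disconnected_graph")
})

test_that("trapezoidal AUC reproduces hand-computed integrals", {
  g <- sparsity_grid()
  expect_equal(auc_trapezoid(g, rep(3, 8)), 0.35 * 3)
  # exact for a linear profile
  expect_equal(auc_trapezoid(g, 2 * g + 1),
               (0.40^2 - 0.05^2) + (0.40 - 0.05))
  expect_equal(auc_trapezoid(g, 1:8), 1.575)
  expect_error(auc_trapezoid(g, c(1:7, NA)), class = "mbn_missing_value")
})

test_that("auc_summary integrates each profile over the stored grid", {
  co <- toy_cohort(n_per_group = 2, n_regions = 8, seed = 3)
  sim <- build_networks(co)
  grid <- sparsity_grid(0.2, 0.4, 0.05)
  m <- compute_metrics(sim, sparsity = grid, null_config = NULL)
  a <- auc_summary(m)
  one <- m |>
    dplyr::filter(subject_id == "S003", metric == "E_glob") |>
    dplyr::arrange(sparsity)
  expect_equal(
    a$auc[a$subject_id == "S003" & a$metric == "E_glob"],
    auc_trapezoid(grid, one$value))
  prof <- m |>
    dplyr::filter(subject_id == "S002", metric == "degree",
                  region_id == 5) |>
    dplyr::arrange(sparsity)
  expect_equal(
    a$auc[a$subject_id == "S002" & a$metric == "degree" &
            !is.na(a$region_id) & a$region_id == 5],
    auc_trapezoid(grid, prof$value))
  # a missing level is an error, not an imputation
  expect_error(auc_summary(dplyr::filter(m, sparsity > 0.2),
                           sparsity = grid),
               class = "mbn_missing_value")
})

test_that("compute_metrics agrees with the standalone metric functions", {
  co <- toy_cohort(n_per_group = 2, n_regions = 10, seed = 21)
  sim <- build_networks(co)
  m <- compute_metrics(sim, sparsity = c(0.25, 0.35),
                       null_config = reference_config(n_ref = 6, seed = 13))
  mat <- similarity_matrix(sim, "S002")
  adj <- threshold_by_sparsity(mat, 0.35)
  gm <- global_metrics(adj, reference_config(n_ref = 6, seed = 13))
  got <- m |>
    dplyr::filter(subject_id == "S002", sparsity == 0.35,
                  level == "global") |>
    tidyr::pivot_wider(names_from = metric, values_from = value)
  expect_equal(got$C_p, gm$C_p, tolerance = 1e-12)
  expect_equal(got$gamma, gm$gamma, tolerance = 1e-12)
  expect_equal(got$lambda, gm$lambda, tolerance = 1e-12)
  expect_equal(got$E_loc, gm$E_loc, tolerance = 1e-12)
  nm <- nodal_metrics(adj)
  gotn <- m |>
    dplyr::filter(subject_id == "S002", sparsity == 0.35,
                  level == "nodal") |>
    tidyr::pivot_wider(id_cols = region_id, names_from = metric,
                       values_from = value)
  expect_equal(gotn$degree, as.numeric(nm$degree))
  expect_equal(gotn$efficiency, nm$efficiency, tolerance = 1e-12)
  expect_equal(gotn$betweenness, nm$betweenness, tolerance = 1e-12)
})
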
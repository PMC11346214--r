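# Synthetic nodal AUC table with a controllable group signal per region.
fake_nodal_auc <- function(metadata, regions, strong = integer(0),
                           seed = 1) {
  set.seed(seed)
  g <- as.numeric(metadata$group == levels(metadata$group)[1])
  rows <- lapply(regions, function(r) {
    shift <- if (r %in% strong) 5 else 0
    lapply(c("degree", "efficiency", "betweenness"), function(met) {
      tibble::tibble(subject_id = metadata$subject_id, level = "nodal",
                     metric = met, region_id = r,
                     auc = rnorm(nrow(metadata)) + shift * g)
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}

fake_metadata <- function(n_per_group = 10, seed = 2) {
  set.seed(seed)
  n <- 2 * n_per_group
  tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    group = factor(rep(c("patient", "control"), each = n_per_group),
                   levels = c("patient", "control")),
    age = runif(n, 5, 13),
    sex = factor(sample(c("male", "female"), n, TRUE))
  )
}

test_that("node-restricted screening returns all pairs of screened nodes", {
  md <- fake_metadata(10)
  auc <- fake_nodal_auc(md, regions = 1:6, strong = c(1, 2, 3), seed = 5)
  scr <- primary_screen(md, auc = auc)
  expect_setequal(attr(scr, "screened_nodes"), c(1, 2, 3))
  expect_equal(nrow(scr), 3)
  expect_equal(paste(scr$region_a, scr$region_b),
               c("1 2", "1 3", "2 3"))
  # any-endpoint rule: every pair touching a screened node
  scr2 <- primary_screen(md, auc = auc, edge_rule = "any")
  expect_equal(nrow(scr2), choose(6, 2) - choose(3, 2))
})

test_that("an effect-free screen returns an empty suprathreshold set", {
  md <- fake_metadata(10, seed = 8)
  auc <- fake_nodal_auc(md, regions = 1:5, strong = integer(0), seed = 41)
  scr <- primary_screen(md, auc = auc, alpha = 1e-6)
  expect_equal(nrow(scr), 0)
  r <- nbs(md, auc = auc, alpha = 1e-6, n_perm = 120, seed = 2)
  expect_equal(nrow(r$components), 0)
})

test_that("edge-wise screening keeps edges below the primary alpha", {
  co <- toy_cohort(n_per_group = 10, n_regions = 6, seed = 31)
  sim <- build_networks(co)
  scr <- primary_screen(co$metadata, similarity = sim, mode = "edge-wise",
                        alpha = 0.2)
  pairs <- dplyr::distinct(sim[, c("region_a", "region_b")])
  ps <- purrr::pmap_dbl(pairs, function(region_a, region_b) {
    d <- dplyr::inner_join(
      sim[sim$region_a == region_a & sim$region_b == region_b, ],
      co$metadata, by = "subject_id")
    ancova_f_test(d, "similarity")$p_value
  })
  want <- pairs[ps < 0.2, ]
  expect_equal(nrow(scr), nrow(want))
  expect_setequal(paste(scr$region_a, scr$region_b),
                  paste(want$region_a, want$region_b))
})

test_that("connected components match hand traces and union-find", {
  cc <- connected_components(
    tibble::tibble(region_a = c(1, 2, 7), region_b = c(2, 3, 8)))
  expect_equal(cc$components$n_edges, c(2L, 1L))
  expect_equal(cc$components$n_nodes, c(3L, 2L))
  expect_equal(nrow(connected_components(
    tibble::tibble(region_a = integer(0),
                   region_b = integer(0)))$components), 0)
  clique <- t(combn(c(2, 5, 8, 9), 2))
  cc4 <- connected_components(
    tibble::tibble(region_a = clique[, 1], region_b = clique[, 2]))
  expect_equal(cc4$components$n_edges, choose(4, 2))

  set.seed(19)
  for (i in 1:20) {
    n_e <- sample(1:25, 1)
    ea <- sample(1:15, n_e, TRUE)
    eb <- sample(1:15, n_e, TRUE)
    keep <- ea != eb
    if (!any(keep)) next
    edges <- tibble::tibble(region_a = pmin(ea, eb)[keep],
                            region_b = pmax(ea, eb)[keep])
    got <- connected_components(edges)
    want <- uf_components(edges$region_a, edges$region_b)
    expect_equal(sort(got$components$n_edges),
                 sort(as.integer(lengths(want))))
    # edges grouped identically
    got_groups <- split(seq_len(nrow(edges)), got$edges$component_id)
    expect_setequal(lapply(unname(got_groups), sort),
                    lapply(unname(want), sort))
  }
})

test_that("permutation p-values follow the add-one formula", {
  md <- fake_metadata(8, seed = 13)
  auc <- fake_nodal_auc(md, regions = 1:8, strong = 1:4, seed = 3)
  r <- nbs(md, auc = auc, n_perm = 199, seed = 7)
  expect_gt(nrow(r$components), 0)
  expect_length(r$null_max_size, 199)
  for (i in seq_len(nrow(r$components))) {
    sz <- r$components$n_edges[i]
    expect_equal(r$components$p_perm[i],
                 (1 + sum(r$null_max_size >= sz)) / 200)
  }
  expect_equal(r$components$p_fdr, bh_fdr(r$components$p_perm))
  expect_true(all(r$components$p_perm >= 1 / 200))
})

test_that("NBS results are deterministic and subject-order invariant", {
  md <- fake_metadata(8, seed = 21)
  auc <- fake_nodal_auc(md, regions = 1:6, strong = 1:3, seed = 9)
  r1 <- nbs(md, auc = auc, n_perm = 150, seed = 5)
  r2 <- nbs(md, auc = auc, n_perm = 150, seed = 5)
  expect_identical(r1$components, r2$components)
  expect_identical(r1$null_max_size, r2$null_max_size)
  shuffle <- sample(nrow(md))
  r3 <- nbs(md[shuffle, ], auc = auc[sample(nrow(auc)), ],
            n_perm = 150, seed = 5)
  expect_identical(r1$components, r3$components)
  r4 <- nbs(md, auc = auc, n_perm = 150, seed = 6)
  expect_false(identical(r1$null_max_size, r4$null_max_size))
})

test_that("NBS warns on coarse permutation counts and tiny groups", {
  md <- fake_metadata(4, seed = 2)
  auc <- fake_nodal_auc(md, regions = 1:4, seed = 6)
  expect_warning(
    expect_warning(nbs(md, auc = auc, n_perm = 50, seed = 1),
                   "permutations"),
    "fewer than 5")
  expect_warning(nbs(md, auc = auc, n_perm = 120, seed = 1),
                 "fewer than 5")
})

test_that("tidy and glance summarise an NBS fit", {
  md <- fake_metadata(8, seed = 33)
  auc <- fake_nodal_auc(md, regions = 1:6, strong = 1:3, seed = 11)
  r <- nbs(md, auc = auc, n_perm = 150, seed = 4)
  expect_identical(tidy(r), r$components)
  g <- glance(r)
  expect_equal(g$n_perm, 150L)
  expect_equal(g$n_components, nrow(r$components))
  expect_equal(g$mode, "node-restricted")
})

test_that("a planted subnetwork yields one dominant significant component", {
  co <- simulate_cohort(
    cohort_config(n_group_a = 15, n_group_b = 15,
                  vertices_per_region = c(30, 60), baseline_sd = 0.2,
                  effect_regions = 1:6, effect_size = 1,
                  effect_type = "exchange", seed = 61),
    toy_scheme(10))
  sim <- build_networks(co)
  a <- auc_summary(compute_metrics(sim, null_config = NULL,
                                   metrics = "nodal"))
  r <- nbs(co$metadata, auc = a, n_perm = 199, seed = 8)
  expect_gt(nrow(r$components), 0)
  top <- r$components[which.max(r$components$n_edges), ]
  expect_lt(top$p_perm, 0.05)
  top_nodes <- unique(unlist(
    r$edges[r$edges$component_id == top$component_id,
            c("region_a", "region_b")]))
  expect_gte(length(intersect(top_nodes, 1:6)), 4)
})
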
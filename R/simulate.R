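#' Configuration for a synthetic morphometry cohort
#'
#' Defines the generating model for a two-group cohort of parcellated
#' gray-matter morphometry. Vertex values for subject \eqn{i}, region \eqn{r},
#' vertex \eqn{v} follow
#' \deqn{x_{irv} = \mu_r + \beta_{age}(age_i - \bar a) + \beta_{sex} m_i +
#'   b_{ir} + \delta_r 1[i \in A] + \epsilon_{irv}}
#' with region-level means \eqn{\mu_r \sim N(\mu_0, \tau^2)}, subject-by-region
#' deviations \eqn{b_{ir} \sim N(0, \omega^2)} and vertex noise
#' \eqn{\epsilon \sim N(0, s^2)}. The planted group effect shifts the mean of
#' each affected region in group A by `effect_size` standard deviations of the
#' subject-by-region scale (\eqn{\delta_r = \pm\, effect\_size \cdot \omega},
#' signs alternating over the affected regions so that distances both within
#' the planted set and between planted and unaffected regions change).
#'
#' Defaults mirror the reference cohort the generator emulates: 61 patients
#' vs 42 controls, ages about 5-13 years, roughly two-thirds male, and vertex
#' counts per region drawn once (an atlas property) from 50-300.
#'
#' @param n_group_a,n_group_b Subject counts for the two groups.
#' @param group_labels Length-2 character vector; first label is the group
#'   receiving the planted effect.
#' @param vertices_per_region Integer range (length 2) from which each
#'   region's vertex count is drawn once per cohort.
#' @param baseline_mean,baseline_sd Mean and spread of the region-level means
#'   \eqn{\mu_r} (arbitrary gray-matter-volume-like units).
#' @param vertex_sd Within-region vertex noise sd.
#' @param subject_sd Subject-by-region deviation sd; also the unit in which
#'   `effect_size` is expressed.
#' @param age_range Length-2 numeric, years; ages drawn uniformly.
#' @param sex_ratio Fraction of male subjects.
#' @param age_slope,sex_effect Linear covariate effects on region means
#'   (units per year, and male-minus-female offset).
#' @param effect_regions Regions carrying the planted group effect: an integer
#'   vector of region ids, or a list of length-2 region-id pairs / two-column
#'   matrix, in which case all regions mentioned are planted.
#' @param effect_size Standardised shift (in units of `subject_sd`) of planted
#'   region means in group A; must be >= 0.
#' @param effect_type How the group effect is planted. `"shift"` moves each
#'   planted region's mean by `effect_size * subject_sd` (signs alternating).
#'   `"exchange"` permutes the baseline means among the planted regions in
#'   group A (a half-rotation of their rank order), i.e. each planted region
#'   is shifted onto another planted region's mean. Because the multiset of
#'   region means is unchanged, the connectivity profile of every unaffected
#'   region has an identical distribution in both groups, which makes the
#'   planted node set the exact ground truth for subnetwork recovery;
#'   `effect_size` only gates the effect (any value > 0 activates it, the
#'   magnitude being set by the spread of the region means). Exchange
#'   planting requires at least two planted regions.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return An object of class `mbn_cohort_config`.
#' @seealso [simulate_cohort()], [planted_effect_profile()]
#' @export
cohort_config <- function(n_group_a = 61L,
                          n_group_b = 42L,
                          group_labels = c("patient", "control"),
                          vertices_per_region = c(50L, 300L),
                          baseline_mean = 0.5,
                          baseline_sd = 0.1,
                          vertex_sd = 0.05,
                          subject_sd = 0.02,
                          age_range = c(5, 13),
                          sex_ratio = 0.66,
                          age_slope = -0.003,
                          sex_effect = 0.01,
                          effect_regions = integer(0),
                          effect_size = 0,
                          effect_type = c("shift", "exchange"),
                          seed = 1L) {
  effect_type <- match.arg(effect_type)
  n_group_a <- as.integer(n_group_a)
  n_group_b <- as.integer(n_group_b)
  if (is.na(n_group_a) || is.na(n_group_b) || n_group_a < 1 || n_group_b < 1) {
    abort("Group sizes must be positive integers.", class = "mbn_config_error")
  }
  if (length(group_labels) != 2 || anyDuplicated(group_labels) > 0) {
    abort("`group_labels` must be two distinct labels.",
          class = "mbn_config_error")
  }
  vertices_per_region <- as.integer(vertices_per_region)
  if (length(vertices_per_region) != 2 || any(vertices_per_region < 1) ||
      vertices_per_region[1] > vertices_per_region[2]) {
    abort("`vertices_per_region` must be an increasing positive range.",
          class = "mbn_config_error")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size < 0) {
    abort("`effect_size` must be a single value >= 0.",
          class = "mbn_config_error")
  }
  planted <- parse_effect_regions(effect_regions)
  if (effect_size > 0 && length(planted$regions) == 0) {
    abort("`effect_regions` must be non-empty when `effect_size` > 0.",
          class = "mbn_config_error")
  }
  if (effect_type == "exchange" && effect_size > 0 &&
      length(planted$regions) < 2) {
    abort("Exchange planting needs at least two planted regions.",
          class = "mbn_config_error")
  }
  if (sex_ratio < 0 || sex_ratio > 1) {
    abort("`sex_ratio` must lie in [0, 1].", class = "mbn_config_error")
  }
  structure(
    list(
      n_group_a = n_group_a, n_group_b = n_group_b,
      group_labels = as.character(group_labels),
      vertices_per_region = vertices_per_region,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      vertex_sd = vertex_sd, subject_sd = subject_sd,
      age_range = as.numeric(age_range), sex_ratio = sex_ratio,
      age_slope = age_slope, sex_effect = sex_effect,
      effect_regions = planted$regions, effect_pairs = planted$pairs,
      effect_size = effect_size, effect_type = effect_type,
      seed = as.integer(seed)
    ),
    class = "mbn_cohort_config"
  )
}

# Group-A mean shifts per region implied by the configured effect. For
# "shift" planting the shift is effect_size * subject_sd with alternating
# signs; for "exchange" planting the planted regions' baseline means are
# rotated by half their rank order, so the multiset of region means is the
# same in both groups.
planted_delta <- function(config, mu, planted_idx) {
  delta <- numeric(length(mu))
  k <- length(planted_idx)
  if (k == 0 || config$effect_size == 0) return(delta)
  if (config$effect_type == "shift") {
    delta[planted_idx] <- rep_len(c(1, -1), k) *
      config$effect_size * config$subject_sd
  } else {
    ord <- planted_idx[order(mu[planted_idx])]
    vals <- mu[ord]
    # Inter-regional distances are roughly symmetric in the region means
    # about their centre, so a region moved onto the mirror image of its old
    # mean keeps a near-identical connectivity profile. Choose the value
    # permutation (rotation of the sorted or reverse-sorted means) that
    # keeps every planted region far from both its old mean and its mirror.
    ctr <- mean(mu)
    mirror <- 2 * ctr - vals
    best <- NULL
    best_score <- -Inf
    for (base in list(vals, rev(vals))) {
      for (shift in seq_len(k - 1)) {
        tgt <- base[(seq_len(k) + shift - 1L) %% k + 1L]
        score <- min(pmin(abs(tgt - vals), abs(tgt - mirror)))
        if (score > best_score + 1e-12) {
          best_score <- score
          best <- tgt
        }
      }
    }
    delta[ord] <- best - vals
  }
  delta
}

# Accepts ids, a list of pairs, or a two-column matrix/data.frame; returns the
# sorted unique planted region ids and any explicitly planted pairs.
parse_effect_regions <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(list(regions = integer(0), pairs = NULL))
  }
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (ncol(x) != 2) abort("Effect-region matrix must have two columns.",
                            class = "mbn_config_error")
    pairs <- matrix(as.integer(x), ncol = 2)
    return(list(regions = sort(unique(as.vector(pairs))), pairs = pairs))
  }
  if (is.list(x)) {
    if (!all(lengths(x) == 2)) {
      abort("Effect-region pairs must each have two region ids.",
            class = "mbn_config_error")
    }
    pairs <- do.call(rbind, lapply(x, as.integer))
    return(list(regions = sort(unique(as.vector(pairs))), pairs = pairs))
  }
  list(regions = sort(unique(as.integer(x))), pairs = NULL)
}

#' @export
print.mbn_cohort_config <- function(x, ...) {
  cat("<mbn_cohort_config>\n")
  cat(sprintf("  groups: %s (n=%d) vs %s (n=%d)\n",
              x$group_labels[1], x$n_group_a, x$group_labels[2], x$n_group_b))
  cat(sprintf("  planted regions: %s (effect_size = %g)\n",
              if (length(x$effect_regions)) {
                paste(x$effect_regions, collapse = ", ")
              } else "none",
              x$effect_size))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate a parcellated morphometry cohort with known ground truth
#'
#' Generates a two-group cohort under the model described in
#' [cohort_config()]. The result bundles the long-format morphometry table,
#' the cohort metadata, and a ground-truth record listing the planted regions,
#' their shift directions, and every region pair whose inter-regional
#' similarity is directly affected (all pairs with at least one planted
#' endpoint). Regeneration with the same config and seed is bit-identical.
#'
#' @param config An [cohort_config()] object.
#' @param scheme A parcellation scheme; defaults to the 116-region
#'   [default_scheme()].
#' @return An object of class `mbn_cohort`: a list with elements
#'   `morphometry` (tibble: subject_id, region_id, vertex_index, value),
#'   `metadata` (tibble: subject_id, group, age, sex), `ground_truth` (list),
#'   `scheme`, and `vertex_counts`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_group_a = 4, n_group_b = 4),
#'                           toy_scheme(6))
#' cohort$metadata
#' @export
simulate_cohort <- function(config, scheme = default_scheme()) {
  if (!inherits(config, "mbn_cohort_config")) {
    abort("`config` must be created by cohort_config().")
  }
  scheme <- validate_scheme(scheme)
  missing_planted <- setdiff(config$effect_regions, scheme$region_id)
  if (length(missing_planted) > 0) {
    abort(paste0("Planted effect regions not in scheme: ",
                 paste(missing_planted, collapse = ", "), "."),
          class = "mbn_config_error")
  }

  R <- nrow(scheme)
  n_a <- config$n_group_a
  n_b <- config$n_group_b
  n <- n_a + n_b

  planted <- config$effect_regions
  planted_idx <- match(planted, scheme$region_id)

  out <- withr::with_seed(config$seed, {
    mu <- rnorm(R, config$baseline_mean, config$baseline_sd)
    counts <- sample(seq(config$vertices_per_region[1],
                         config$vertices_per_region[2]),
                     R, replace = TRUE)
    age <- runif(n, config$age_range[1], config$age_range[2])
    male <- rbinom(n, 1, config$sex_ratio)
    b <- matrix(rnorm(n * R, 0, config$subject_sd), nrow = n)

    delta <- planted_delta(config, mu, planted_idx)
    in_a <- c(rep(1, n_a), rep(0, n_b))
    # n x R matrix of subject-by-region means
    m <- outer(rep(1, n), mu) +
      config$age_slope * (age - mean(config$age_range)) +
      config$sex_effect * male +
      b +
      outer(in_a, delta)

    region_idx <- rep(seq_len(R), counts)
    vertex_seq <- sequence(counts)
    v_total <- length(region_idx)
    means_long <- as.vector(t(m[, region_idx, drop = FALSE]))
    values <- rnorm(n * v_total, mean = means_long, sd = config$vertex_sd)
    list(mu = mu, counts = counts, age = age, male = male, delta = delta,
         region_idx = region_idx, vertex_seq = vertex_seq, values = values)
  })

  subject_id <- sprintf("S%03d", seq_len(n))
  group <- factor(rep(config$group_labels, c(n_a, n_b)),
                  levels = config$group_labels)
  metadata <- tibble::tibble(
    subject_id = subject_id,
    group = group,
    age = out$age,
    sex = factor(ifelse(out$male == 1, "male", "female"),
                 levels = c("female", "male"))
  )
  v_total <- length(out$region_idx)
  morphometry <- tibble::tibble(
    subject_id = rep(subject_id, each = v_total),
    region_id = rep(scheme$region_id[out$region_idx], n),
    vertex_index = rep(out$vertex_seq, n),
    value = out$values
  )

  affected_pairs <- affected_pair_table(planted, scheme$region_id)
  planted_shift <- out$delta[planted_idx]
  ground_truth <- list(
    planted_regions = planted,
    planted_signs = sign(planted_shift),
    planted_delta = planted_shift,
    planted_pairs = config$effect_pairs,
    affected_pairs = affected_pairs,
    effect_size = config$effect_size,
    effect_type = config$effect_type,
    region_means = out$mu,
    seed = config$seed
  )

  structure(
    list(
      morphometry = morphometry,
      metadata = metadata,
      ground_truth = ground_truth,
      scheme = scheme,
      vertex_counts = tibble::tibble(region_id = scheme$region_id,
                                     n_vertices = out$counts),
      config = config
    ),
    class = "mbn_cohort"
  )
}

# All unordered pairs with at least one planted endpoint (region_a < region_b).
affected_pair_table <- function(planted, region_ids) {
  if (length(planted) == 0) {
    return(tibble::tibble(region_a = integer(0), region_b = integer(0)))
  }
  grid <- expand.grid(region_a = planted, region_b = region_ids)
  grid <- grid[grid$region_a != grid$region_b, ]
  a <- pmin(grid$region_a, grid$region_b)
  b <- pmax(grid$region_a, grid$region_b)
  dplyr::distinct(tibble::tibble(region_a = a, region_b = b)) |>
    dplyr::arrange(.data$region_a, .data$region_b)
}

#' @export
print.mbn_cohort <- function(x, ...) {
  cat("<mbn_cohort>\n")
  cat(sprintf("  %d subjects (%s), %d regions, %d morphometry rows\n",
              nrow(x$metadata),
              paste(sprintf("%s n=%d", levels(x$metadata$group),
                            table(x$metadata$group)), collapse = " vs "),
              nrow(x$scheme), nrow(x$morphometry)))
  if (length(x$ground_truth$planted_regions)) {
    cat(sprintf("  planted effect: %d regions, effect_size = %g\n",
                length(x$ground_truth$planted_regions),
                x$ground_truth$effect_size))
  } else {
    cat("  no planted group effect (null cohort)\n")
  }
  invisible(x)
}

#' Empirically measure the similarity shift induced by a planted effect
#'
#' The planted group effect acts on vertex-value distributions, and its
#' consequence for inter-regional similarity has no simple closed form (the
#' min-max normalisation couples all pairs). This helper records the induced
#' shift empirically: it regenerates a large cohort under the same generating
#' parameters and returns the group difference in mean similarity for each
#' directly affected pair.
#'
#' @param config An [cohort_config()] object (its group sizes are overridden).
#' @param scheme Parcellation scheme.
#' @param n_per_group Subjects per group for the Monte-Carlo estimate.
#' @param seed Seed for the regeneration (independent of `config$seed`).
#' @return A tibble with columns `region_a`, `region_b`,
#'   `delta_similarity` (group A minus group B mean edge similarity).
#' @export
planted_effect_profile <- function(config, scheme = default_scheme(),
                                   n_per_group = 200L, seed = 1000L) {
  big <- config
  big$n_group_a <- as.integer(n_per_group)
  big$n_group_b <- as.integer(n_per_group)
  big$seed <- as.integer(seed)
  cohort <- simulate_cohort(big, scheme)
  sim <- build_networks(cohort)
  sim |>
    dplyr::inner_join(cohort$ground_truth$affected_pairs,
                      by = c("region_a", "region_b")) |>
    dplyr::left_join(cohort$metadata[, c("subject_id", "group")],
                     by = "subject_id") |>
    dplyr::group_by(.data$region_a, .data$region_b, .data$group) |>
    dplyr::summarise(mean_sim = mean(.data$similarity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_sim") |>
    dplyr::mutate(delta_similarity =
                    .data[[big$group_labels[1]]] -
                    .data[[big$group_labels[2]]]) |>
    dplyr::select("region_a", "region_b", "delta_similarity")
}

#' Clinical-variable generating model
#'
#' Each clinical variable is a linear function of a subject-level planted
#' network feature plus Gaussian noise:
#' \eqn{score = intercept + slope \times feature + N(0, noise\_sd^2)}.
#' The feature is the subject's mean edge similarity over the planted
#' (directly affected) region pairs, or over all pairs when the cohort has no
#' planted effect. With `noise_sd = 0` the mapping is exact.
#'
#' The default model reproduces the marginal scale of the reference cohort's
#' clinical panel (serum IGF-1 in ng/ml, stimulated GH peak in ug/l, and a
#' total behaviour-checklist score) with zero coupling to the network.
#'
#' @param ... Named variable specifications, each a list or named numeric
#'   vector with elements `intercept`, `slope`, `noise_sd`.
#' @return An object of class `mbn_clinical_model`.
#' @seealso [attach_clinical_scores()], [clinical_noise_sd()]
#' @export
clinical_model <- function(...) {
  vars <- list(...)
  if (length(vars) == 0 || is.null(names(vars)) || any(names(vars) == "")) {
    abort("Provide named clinical-variable specifications.")
  }
  vars <- lapply(vars, function(v) {
    v <- as.list(v)
    need <- c("intercept", "slope", "noise_sd")
    if (!all(need %in% names(v))) {
      abort("Each clinical variable needs intercept, slope and noise_sd.")
    }
    v <- v[need]
    if (!all(vapply(v, is.finite, logical(1))) || v$noise_sd < 0) {
      abort("Clinical model parameters must be finite with noise_sd >= 0.")
    }
    v
  })
  structure(vars, class = "mbn_clinical_model")
}

#' @rdname clinical_model
#' @export
default_clinical_model <- function() {
  clinical_model(
    igf1 = list(intercept = 171.89, slope = 0, noise_sd = 80.71),
    gh_peak = list(intercept = 3.14, slope = 0, noise_sd = 1.57),
    cbcl_total = list(intercept = 43.58, slope = 0, noise_sd = 24.66)
  )
}

#' Noise level achieving a target population correlation
#'
#' For `score = intercept + slope * feature + noise`, the population
#' correlation between score and feature is
#' \eqn{r = |slope| \sigma_f / \sqrt{slope^2 \sigma_f^2 + \sigma_n^2}}.
#' This returns the noise sd giving a requested `r`.
#'
#' @param slope Linear coefficient on the feature.
#' @param feature_sd Standard deviation of the feature.
#' @param r Target correlation in (0, 1].
#' @return The noise standard deviation.
#' @export
clinical_noise_sd <- function(slope, feature_sd, r) {
  if (r <= 0 || r > 1) abort("`r` must lie in (0, 1].")
  abs(slope) * feature_sd * sqrt(1 / r^2 - 1)
}

#' Attach simulated clinical scores to a cohort
#'
#' Populates clinical columns of the cohort metadata from the generating model
#' in [clinical_model()]. The planted network feature is each subject's mean
#' edge similarity over the ground-truth affected pairs (all pairs when no
#' effect is planted), so simulated clinical scores can carry a known
#' association with network properties.
#'
#' @param cohort An `mbn_cohort`.
#' @param model An [clinical_model()]; defaults to the reference marginals
#'   with zero network coupling.
#' @param similarity Optional precomputed similarity table from
#'   [build_networks()] (avoids rebuilding networks).
#' @param groups Group labels whose subjects receive scores (others get `NA`);
#'   defaults to the first (patient) group, mirroring a clinical panel
#'   collected only in patients.
#' @param seed Seed for the noise draws.
#' @return The cohort with clinical columns added to `$metadata` and the
#'   feature stored as column `planted_feature`.
#' @export
attach_clinical_scores <- function(cohort, model = default_clinical_model(),
                                   similarity = NULL,
                                   groups = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "mbn_cohort"))
  if (!inherits(model, "mbn_clinical_model")) {
    abort("`model` must be created by clinical_model().")
  }
  if (is.null(similarity)) similarity <- build_networks(cohort)
  groups <- groups %||% levels(cohort$metadata$group)[1]

  pairs <- cohort$ground_truth$affected_pairs
  feat_tbl <- if (nrow(pairs) > 0) {
    dplyr::inner_join(similarity, pairs, by = c("region_a", "region_b"))
  } else {
    similarity
  }
  feature <- feat_tbl |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(planted_feature = mean(.data$similarity),
                     .groups = "drop")

  md <- dplyr::left_join(cohort$metadata, feature, by = "subject_id")
  in_target <- md$group %in% groups
  n <- nrow(md)
  scores <- withr::with_seed(seed, {
    lapply(model, function(v) {
      v$intercept + v$slope * md$planted_feature + rnorm(n, 0, v$noise_sd)
    })
  })
  for (nm in names(scores)) {
    col <- scores[[nm]]
    col[!in_target] <- NA_real_
    md[[nm]] <- col
  }
  cohort$metadata <- md
  cohort
}
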
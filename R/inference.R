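#' Covariate-adjusted group comparison (ANCOVA partial F test)
#'
#' Fits the linear model `response ~ group + covariates` and returns the
#' partial F test for the group factor: the comparison of residual sums of
#' squares between the covariate-only model and the full model, on
#' \eqn{(1, n - p)} degrees of freedom. The reported `estimate` is the
#' covariate-adjusted mean difference (first group minus second group) and
#' `direction` states which group is larger after adjustment.
#'
#' @param data A data frame with the response, a two-level group column and
#'   the covariate columns.
#' @param response Name of the response column.
#' @param group Name of the group column (2 levels; factors keep their level
#'   order, otherwise first appearance order).
#' @param covariates Covariate column names; categorical covariates are
#'   expanded to indicator columns. `NULL` gives the unadjusted two-sample
#'   comparison (the pooled-variance F, equal to the squared t statistic).
#' @return A one-row tibble with columns `response`, `n`, `statistic`, `df1`,
#'   `df2`, `p_value`, `estimate`, `direction`.
#' @examples
#' d <- data.frame(y = rnorm(40), group = rep(c("a", "b"), 20),
#'                 age = runif(40, 5, 13),
#'                 sex = rep(c("m", "f"), each = 20))
#' ancova_f_test(d, "y")
#' @export
ancova_f_test <- function(data, response, group = "group",
                          covariates = c("age", "sex")) {
  cols <- c(response, group, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", "), "."),
          class = "mbn_validation_error")
  }
  y <- data[[response]]
  if (!is.numeric(y) || anyNA(y)) {
    abort("Response must be numeric with no missing values.",
          class = "mbn_validation_error")
  }
  g <- group_indicator(data[[group]])
  Z <- covariate_matrix(data, covariates)
  check_design_rank(g$indicator, Z, n = length(y))

  fit <- ancova_f_matrix(matrix(y, ncol = 1), g$indicator, Z)
  tibble::tibble(
    response = response,
    n = length(y),
    statistic = fit$statistic[1],
    df1 = 1L,
    df2 = fit$df2,
    p_value = fit$p_value[1],
    estimate = fit$estimate[1],
    direction = direction_label(fit$estimate[1], g$levels)
  )
}

group_indicator <- function(g) {
  f <- if (is.factor(g)) droplevels(g) else factor(g, levels = unique(g))
  if (nlevels(f) != 2 || anyNA(f)) {
    abort("Group column must have exactly 2 levels and no missing values.",
          class = "mbn_validation_error")
  }
  if (min(table(f)) < 2) {
    abort("Each group needs at least 2 subjects.",
          class = "mbn_validation_error")
  }
  # indicator = 1 for the FIRST level, so estimate = first minus second
  list(indicator = as.numeric(f == levels(f)[1]), levels = levels(f))
}

direction_label <- function(estimate, levels) {
  if (is.na(estimate) || estimate == 0) return(NA_character_)
  if (estimate > 0) paste0(levels[1], " > ", levels[2])
  else paste0(levels[1], " < ", levels[2])
}

# Expand covariate columns to a numeric matrix (factors/characters become
# 0/1 indicators against their first level). NULL -> zero-column matrix.
covariate_matrix <- function(data, covariates) {
  n <- nrow(data)
  if (is.null(covariates) || length(covariates) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  cols <- lapply(covariates, function(nm) {
    v <- data[[nm]]
    if (anyNA(v)) {
      abort(sprintf("Covariate `%s` has missing values.", nm),
            class = "mbn_validation_error")
    }
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- if (is.factor(v)) droplevels(v) else factor(v)
      if (nlevels(f) < 2) {
        # constant factor: a zero column, caught by the rank check
        m <- matrix(0, length(f), 1,
                    dimnames = list(NULL, paste0(nm, levels(f))))
      } else {
        m <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(nm, levels(f)[-1])
      }
    }
    m
  })
  do.call(cbind, cols)
}

check_design_rank <- function(g, Z, n) {
  X <- cbind(`(Intercept)` = 1, group = g, Z)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[seq.int(q$rank + 1L, ncol(X))]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(aliased, collapse = ", "), "."),
          class = "mbn_rank_error")
  }
  invisible(X)
}

# Vectorised ANCOVA over many response columns sharing one design.
# Y: n x m response matrix; g: 0/1 indicator; Z: covariate matrix.
ancova_f_matrix <- function(Y, g, Z) {
  n <- nrow(Y)
  X1 <- cbind(1, g, Z)
  X0 <- cbind(1, Z)
  q1 <- qr(X1)
  q0 <- qr(X0)
  res1 <- qr.resid(q1, Y)
  res0 <- qr.resid(q0, Y)
  rss1 <- colSums(res1^2)
  rss0 <- colSums(res0^2)
  df2 <- n - ncol(X1)
  if (df2 < 1) abort("Not enough residual degrees of freedom.",
                     class = "mbn_validation_error")
  fstat <- (rss0 - rss1) / (rss1 / df2)
  # constant (or perfectly covariate-explained) responses: no group evidence
  scale <- pmax(colSums(Y^2), 1)
  flat <- rss0 <= 1e-12 * scale
  fstat[flat] <- 0
  p <- pf(fstat, 1, df2, lower.tail = FALSE)
  p[flat] <- 1
  beta <- qr.coef(q1, Y)
  list(statistic = unname(fstat), p_value = unname(p),
       estimate = unname(beta[2, ]), df2 = df2)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; the input order
#' is preserved. Thin, validated interface over `stats::p.adjust(method =
#' "BH")` so that every multiple-testing correction in the package goes
#' through one place.
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) {
    abort("`p` must contain at least one p-value.",
          class = "mbn_validation_error")
  }
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].", class = "mbn_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of `x` and `y` after regressing each on the
#' covariates (with intercept). The test statistic is
#' \eqn{t = r\sqrt{(n-2-k)/(1-r^2)}} on \eqn{n - 2 - k} degrees of freedom,
#' where \eqn{k} is the number of covariate columns after expansion.
#' Constant covariate columns are dropped (the partial correlation then
#' equals the plain correlation). Rows with missing values in any involved
#' column are dropped and the returned `n` reflects the rows used.
#'
#' @param data A data frame.
#' @param x,y Column names of the two variables to correlate.
#' @param covariates Covariate column names (default age and sex).
#' @return A one-row tibble with `x`, `y`, `n`, `df`, `estimate` (partial r),
#'   `statistic` (t), `p_value`.
#' @export
partial_correlation <- function(data, x, y, covariates = c("age", "sex")) {
  cols <- c(x, y, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", "), "."),
          class = "mbn_validation_error")
  }
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  Z <- covariate_matrix(d, covariates)
  const <- apply(Z, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    inform(paste0("Dropping constant covariate column(s): ",
                  paste(colnames(Z)[const], collapse = ", "), "."))
    Z <- Z[, !const, drop = FALSE]
  }
  k <- ncol(Z)
  if (n <= k + 3) {
    abort("Too few complete observations for the requested covariates.",
          class = "mbn_validation_error")
  }
  X <- cbind(1, Z)
  rx <- qr.resid(qr(X), as.numeric(d[[x]]))
  ry <- qr.resid(qr(X), as.numeric(d[[y]]))
  tol_x <- 1e-10 * max(abs(d[[x]]), 1)
  tol_y <- 1e-10 * max(abs(d[[y]]), 1)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y) {
    abort("Zero residual variance; partial correlation is undefined.",
          class = "mbn_validation_error")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tval), df)
  if (abs(r) >= 1) pval <- 0
  tibble::tibble(x = x, y = y, n = n, df = df, estimate = r,
                 statistic = tval, p_value = pval)
}

#' Compare AUC network metrics between groups with covariate adjustment
#'
#' Runs the ANCOVA group test of [ancova_f_test()] for every metric in an
#' AUC table and applies Benjamini-Hochberg FDR control in separate families:
#' the global metrics form one family, and each nodal metric type (degree,
#' efficiency, betweenness across all regions) forms its own family.
#'
#' @param auc An `mbn_auc` table from [auc_summary()].
#' @param metadata Cohort metadata with `subject_id`, the group column and
#'   covariates.
#' @param group,covariates Column names in `metadata`.
#' @return A tibble of class `mbn_group_test` with columns `level`, `metric`,
#'   `region_id`, `family`, `n`, `statistic`, `df1`, `df2`, `p_value`,
#'   `p_fdr`, `estimate`, `direction`.
#' @export
compare_groups <- function(auc, metadata, group = "group",
                           covariates = c("age", "sex")) {
  md <- dplyr::arrange(metadata, .data$subject_id)
  wide <- auc |>
    dplyr::mutate(key = paste(.data$level, .data$metric,
                              dplyr::coalesce(as.character(.data$region_id),
                                              "global"),
                              sep = "|")) |>
    dplyr::select("subject_id", "key", "auc") |>
    tidyr::pivot_wider(names_from = "key", values_from = "auc") |>
    dplyr::arrange(.data$subject_id)
  if (!identical(wide$subject_id, md$subject_id)) {
    abort("`auc` and `metadata` must cover the same subjects.",
          class = "mbn_validation_error")
  }
  Y <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(Y)) abort("AUC table has missing values.",
                      class = "mbn_validation_error")
  g <- group_indicator(md[[group]])
  Z <- covariate_matrix(md, covariates)
  check_design_rank(g$indicator, Z, n = nrow(Y))
  fit <- ancova_f_matrix(Y, g$indicator, Z)

  keys <- strsplit(colnames(Y), "|", fixed = TRUE)
  out <- tibble::tibble(
    level = vapply(keys, `[`, "", 1),
    metric = vapply(keys, `[`, "", 2),
    region_id = suppressWarnings(
      as.integer(ifelse(vapply(keys, `[`, "", 3) == "global", NA,
                        vapply(keys, `[`, "", 3)))),
    n = nrow(Y),
    statistic = unname(fit$statistic),
    df1 = 1L,
    df2 = fit$df2,
    p_value = unname(fit$p_value),
    estimate = unname(fit$estimate),
    direction = vapply(unname(fit$estimate), direction_label, "",
                       levels = g$levels)
  )
  out$family <- ifelse(out$level == "global", "global",
                       paste0("nodal_", out$metric))
  out <- out |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_fdr = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$level, .data$metric, .data$region_id)
  class(out) <- c("mbn_group_test", class(out))
  attr(out, "group_levels") <- g$levels
  out
}

#' @export
glance.mbn_group_test <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_families = length(unique(x$family)),
    n_significant_fdr = sum(x$p_fdr < 0.05),
    min_p_fdr = min(x$p_fdr)
  )
}

#' Partial correlations between network metrics and clinical variables
#'
#' For each requested (metric, clinical variable) combination, computes the
#' partial correlation of the metric AUC with the clinical score controlling
#' for age and sex, within one group (clinical panels are typically collected
#' in patients only). P-values are reported raw and flagged as uncorrected,
#' mirroring the exploratory treatment of clinical correlations.
#'
#' @param auc An `mbn_auc` table.
#' @param metadata Cohort metadata including the clinical columns.
#' @param clinical_vars Clinical column names in `metadata`.
#' @param metrics Optional data frame with columns `level`, `metric` and
#'   (optionally) `region_id` selecting the metrics to correlate (e.g. the
#'   significant rows of [compare_groups()]); default all metrics.
#' @param group_label Group whose subjects enter the correlation; defaults to
#'   the first group level in `metadata`.
#' @param covariates Covariates to control for.
#' @return A tibble with `clinical_var`, `level`, `metric`, `region_id`, `n`,
#'   `df`, `estimate`, `statistic`, `p_value`, `correction` (always
#'   `"uncorrected"`).
#' @export
correlate_clinical <- function(auc, metadata, clinical_vars,
                               metrics = NULL,
                               group_label = NULL,
                               covariates = c("age", "sex")) {
  missing <- setdiff(clinical_vars, names(metadata))
  if (length(missing) > 0) {
    abort(paste0("Clinical column(s) not in metadata: ",
                 paste(missing, collapse = ", "), "."),
          class = "mbn_validation_error")
  }
  grp <- metadata$group
  group_label <- group_label %||%
    (if (is.factor(grp)) levels(grp)[1] else unique(grp)[1])
  md <- metadata[metadata$group == group_label, , drop = FALSE]

  sel <- auc
  if (!is.null(metrics)) {
    by_cols <- intersect(c("level", "metric", "region_id"), names(metrics))
    sel <- dplyr::inner_join(
      auc, dplyr::distinct(metrics[, by_cols, drop = FALSE]), by = by_cols)
  }
  combos <- dplyr::distinct(sel[, c("level", "metric", "region_id")])
  rows <- purrr::pmap(combos, function(level, metric, region_id) {
    one <- sel[sel$level == level & sel$metric == metric &
                 (is.na(region_id) | sel$region_id %in% region_id), ]
    d <- dplyr::inner_join(md, one[, c("subject_id", "auc")],
                           by = "subject_id")
    purrr::map(clinical_vars, function(cv) {
      pc <- partial_correlation(d, cv, "auc", covariates)
      tibble::tibble(clinical_var = cv, level = level, metric = metric,
                     region_id = region_id, n = pc$n, df = pc$df,
                     estimate = pc$estimate, statistic = pc$statistic,
                     p_value = pc$p_value, correction = "uncorrected")
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
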
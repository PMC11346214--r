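make_design <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    y = rnorm(n),
    group = factor(rep(c("patient", "control"), each = n / 2),
                   levels = c("patient", "control")),
    age = runif(n, 5, 13),
    sex = factor(sample(c("male", "female"), n, replace = TRUE))
  )
}

test_that("ANCOVA partial F matches the nested-model comparison from lm", {
  d <- make_design(60, seed = 4)
  d$y <- d$y + 0.8 * (d$group == "patient") + 0.1 * d$age
  got <- ancova_f_test(d, "y")
  full <- stats::lm(y ~ group + age + sex, data = d)
  red <- stats::lm(y ~ age + sex, data = d)
  want <- stats::anova(red, full)
  expect_equal(got$statistic, want$F[2], tolerance = 1e-10)
  expect_equal(got$p_value, want$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(got$df2, 60 - 4)
  # adjusted difference: patient-minus-control coefficient
  expect_equal(got$estimate, -unname(coef(full)["groupcontrol"]),
               tolerance = 1e-10)
  expect_match(got$direction, "patient > control")
})

test_that("without covariates the ANCOVA F equals the pooled-variance t^2", {
  d <- make_design(30, seed = 9)
  got <- ancova_f_test(d, "y", covariates = NULL)
  tt <- stats::t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("a constant response gives F = 0 and p = 1", {
  d <- make_design(20, seed = 2)
  d$y <- 5
  got <- ancova_f_test(d, "y")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
})

test_that("rank-deficient designs name the collinear column", {
  d <- make_design(20, seed = 3)
  d$sex <- factor(rep("male", 20), levels = c("female", "male"))
  err <- expect_error(ancova_f_test(d, "y"), class = "mbn_rank_error")
  expect_match(conditionMessage(err), "sex")
})

test_that("the vectorised ANCOVA agrees with per-response lm fits", {
  d <- make_design(36, seed = 7)
  Y <- cbind(a = rnorm(36), b = d$age + rnorm(36),
             c = 2 * (d$group == "patient") + rnorm(36))
  g <- as.numeric(d$group == "patient")
  Z <- cbind(age = d$age, sexmale = as.numeric(d$sex == "male"))
  fit <- mbnet:::ancova_f_matrix(Y, g, Z)
  for (j in 1:3) {
    dd <- cbind(d, yy = Y[, j])
    ref <- ancova_f_test(dd, "yy")
    expect_equal(unname(fit$statistic[j]), ref$statistic, tolerance = 1e-10)
    expect_equal(unname(fit$p_value[j]), ref$p_value, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the hand-worked step-up example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.003, 0.04, 0.3, 0.0001, 0.9)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  # permutation invariance up to reordering
  perm <- sample(5)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(numeric(0)), class = "mbn_validation_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mbn_validation_error")
})

test_that("partial correlation equals the residual-based oracle", {
  set.seed(12)
  n <- 50
  d <- data.frame(age = runif(n, 5, 13),
                  sex = factor(sample(c("m", "f"), n, TRUE)))
  d$x <- 0.3 * d$age + rnorm(n)
  d$y <- 0.2 * d$age - 0.5 * (d$sex == "m") + 0.4 * d$x + rnorm(n)
  got <- partial_correlation(d, "x", "y")
  rx <- resid(lm(x ~ age + sex, data = d))
  ry <- resid(lm(y ~ age + sex, data = d))
  r <- cor(rx, ry)
  expect_equal(got$estimate, r, tolerance = 1e-10)
  df <- n - 2 - 2
  tval <- r * sqrt(df / (1 - r^2))
  expect_equal(got$statistic, tval, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(tval), df), tolerance = 1e-10)
  expect_equal(got$df, df)
})

test_that("partial correlation degenerates gracefully", {
  set.seed(4)
  d <- data.frame(x = rnorm(30), age = runif(30, 5, 13))
  d$y <- d$x
  got <- partial_correlation(d, "x", "y", covariates = "age")
  expect_equal(got$estimate, 1, tolerance = 1e-12)
  expect_equal(got$p_value, 0)
  # constant covariates reduce to the plain correlation
  d$z <- rnorm(30)
  d$const <- 1
  expect_message(
    got2 <- partial_correlation(d, "x", "z", covariates = "const"),
    "constant")
  expect_equal(got2$estimate, cor(d$x, d$z), tolerance = 1e-12)
  d$w <- 5
  expect_error(
    suppressMessages(partial_correlation(d, "x", "w",
                                         covariates = "const")),
    class = "mbn_validation_error")
})

test_that("sample partial correlations track a planted population value", {
  set.seed(71)
  rho <- 0.35
  n <- 61
  zs <- replicate(300, {
    age <- runif(n, 5, 13)
    f <- 0.02 * age + rnorm(n)
    y <- 0.01 * age + rho / sqrt(1 - rho^2) * f + rnorm(n)
    d <- data.frame(x = f, y = y, age = age)
    atanh(partial_correlation(d, "x", "y", covariates = "age")$estimate)
  })
  se <- 1 / sqrt(n - 3 - 1)
  expect_lt(abs(mean(zs) - atanh(rho)), 3 * se / sqrt(300) + 0.02)
})

test_that("compare_groups corrects in separate metric families", {
  co <- toy_cohort(n_per_group = 8, n_regions = 6, seed = 17)
  sim <- build_networks(co)
  m <- compute_metrics(sim, sparsity = sparsity_grid(0.25, 0.4, 0.05),
                       null_config = NULL)
  a <- auc_summary(m)
  res <- compare_groups(a, co$metadata)
  expect_s3_class(res, "mbn_group_test")
  expect_setequal(unique(res$family),
                  c("global", "nodal_degree", "nodal_efficiency",
                    "nodal_betweenness"))
  for (fam in unique(res$family)) {
    rows <- res[res$family == fam, ]
    expect_equal(rows$p_fdr, bh_fdr(rows$p_value))
  }
  # every test is the single-response ANCOVA
  one <- res[res$level == "global" & res$metric == "E_glob", ]
  d <- dplyr::inner_join(
    a[a$metric == "E_glob", c("subject_id", "auc")],
    co$metadata, by = "subject_id")
  ref <- ancova_f_test(d, "auc")
  expect_equal(one$statistic, ref$statistic, tolerance = 1e-10)
  expect_equal(one$p_value, ref$p_value, tolerance = 1e-10)
  g <- glance(res)
  expect_equal(g$n_tests, nrow(res))
})

test_that("clinical correlations are flagged uncorrected and group-restricted", {
  co <- toy_cohort(n_per_group = 12, n_regions = 6, seed = 23)
  sim <- build_networks(co)
  co <- attach_clinical_scores(co, similarity = sim, seed = 3)
  a <- auc_summary(compute_metrics(sim,
                                   sparsity = sparsity_grid(0.25, 0.4, 0.05),
                                   null_config = NULL))
  cc <- correlate_clinical(a, co$metadata, c("igf1", "gh_peak"),
                           metrics = data.frame(level = "global",
                                                metric = "E_glob"))
  expect_equal(nrow(cc), 2)
  expect_true(all(cc$correction == "uncorrected"))
  expect_true(all(cc$n == 12)) # patients only
})
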
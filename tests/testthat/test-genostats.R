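make_cohort <- function(n_e34 = 126, n_e44 = 8, n_e33 = 291, n_e2 = 74) {
  n <- n_e34 + n_e44 + n_e33 + n_e2
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             age = runif(n, 18, 88),
             genotype = rep(c("e3/e4", "e4/e4", "e3/e3", "e2-carrier"),
                            c(n_e34, n_e44, n_e33, n_e2)),
             stringsAsFactors = FALSE)
}

test_that("genotype grouping reproduces the published class arithmetic", {
  set.seed(1)
  g <- suppressMessages(group_genotypes(make_cohort()))
  expect_identical(nrow(g), 425L)                       # retained total
  expect_identical(sum(g$group == "e4+"), 134L)         # 126 + 8
  expect_identical(sum(g$group == "e3/e3"), 291L)
  expect_identical(levels(g$group), c("e3/e3", "e4+"))
  expect_message(group_genotypes(make_cohort()), "74")
})

test_that("epsilon-2-only cohorts empty out and unknown strings error", {
  only_e2 <- data.frame(subject_id = "a", age = 30, genotype = "e2-carrier")
  expect_identical(nrow(suppressMessages(group_genotypes(only_e2))), 0L)
  bad <- data.frame(subject_id = "a", age = 30, genotype = "e5/e5")
  expect_error(group_genotypes(bad), "e5/e5")
})

test_that("IQR outlier flags match hand-computed fences", {
  # constant-age fit degrades to an intercept; residuals (-20 x4, 80)
  flags <- flag_outliers_iqr(c(0, 0, 0, 0, 100), rep(50, 5))
  expect_identical(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # identical values: zero IQR, fences collapse, nothing flagged
  expect_false(any(flag_outliers_iqr(rep(7, 10), runif(10, 18, 88))))
})

test_that("IQR flags agree with a brute-force fence oracle on random data", {
  for (r in 1:20) {
    set.seed(100 + r)
    n <- 50
    age <- runif(n, 18, 88)
    y <- rnorm(n) + 0.02 * age + ifelse(runif(n) < 0.1, rnorm(n, 0, 8), 0)
    got <- flag_outliers_iqr(y, age)
    # oracle: residuals via stats::lm, quartiles via stats::quantile
    res <- stats::resid(stats::lm(y ~ age + I(age^2)))
    q1 <- stats::quantile(res, 0.25); q3 <- stats::quantile(res, 0.75)
    iqr <- q3 - q1
    oracle <- res < q1 - 1.5 * iqr | res > q3 + 1.5 * iqr
    expect_identical(got, unname(oracle))
    # two-sided fences are symmetric under residual negation
    expect_identical(flag_outliers_iqr(-y, age), got)
  }
})

test_that("model estimates match closed-form normal equations on a hand dataset", {
  y <- c(1.0, 2.2, 1.4, 3.1, 0.4, 2.0, 2.6, 1.1, 0.9, 3.3)
  age <- c(20, 30, 40, 50, 60, 70, 80, 25, 35, 45)
  grp <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1)
  fit <- fit_genotype_age_model(y, age, grp, remove_outliers = FALSE,
                                bf_terms = character(0), dv_name = "hand")
  # oracle: explicit normal equations with the same design construction
  za <- (age - mean(age)) / sd(age)
  q <- za^2; zq <- (q - mean(q)) / sd(q)
  X <- cbind(1, za, zq, grp, grp * za, grp * zq)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (10 - 6)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit$terms$estimate, as.numeric(beta), tolerance = 1e-10)
  expect_equal(fit$terms$se, unname(se), tolerance = 1e-10)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  adj <- 1 - (1 - r2) * 9 / 4
  expect_equal(fit$adj_r2, adj, tolerance = 1e-10)
  expect_identical(fit$df, 4L)
  expect_identical(fit$terms$term,
                   c("intercept", "age_linear", "age_quadratic", "apoe",
                     "apoe_x_age", "apoe_x_age2"))
})

test_that("an injected genotype main effect is recovered across replicates", {
  est <- vapply(1:200, function(r) {
    set.seed(2000 + r)
    n <- 400
    age <- runif(n, 18, 88)
    grp <- rbinom(n, 1, 0.32)
    y <- 0.5 * grp + rnorm(n)
    fit <- fit_genotype_age_model(y, age, grp, remove_outliers = FALSE,
                                  bf_terms = character(0))
    fit$terms$estimate[fit$terms$term == "apoe"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("regressors are standardised and p-values scale-free", {
  set.seed(5)
  n <- 120
  age <- runif(n, 18, 88); grp <- rbinom(n, 1, 0.4); y <- rnorm(n)
  fit <- fit_genotype_age_model(y, age, grp, bf_terms = character(0))
  d <- fit$data
  za <- (d$age - mean(d$age)) / sd(d$age)
  expect_equal(mean(za), 0, tolerance = 1e-12)
  expect_equal(sd(za), 1, tolerance = 1e-12)
  # pure rescaling leaves every t and p unchanged; an added constant moves
  # only the intercept
  fit2 <- fit_genotype_age_model(3 * y, age, grp, bf_terms = character(0))
  expect_equal(fit$terms$p, fit2$terms$p, tolerance = 1e-9)
  expect_equal(fit$terms$t, fit2$terms$t, tolerance = 1e-9)
  fit3 <- fit_genotype_age_model(3 * y + 7, age, grp, bf_terms = character(0))
  expect_equal(fit$terms$p[-1], fit3$terms$p[-1], tolerance = 1e-9)
})

test_that("degenerate phenotype inputs raise informative errors", {
  expect_error(fit_genotype_age_model(rnorm(10), runif(10, 18, 88),
                                      rep(1, 10)),
               "both genotype groups")
  expect_error(fit_genotype_age_model(rnorm(6), runif(6, 18, 88),
                                      c(0, 0, 0, 1, 1, 1),
                                      remove_outliers = FALSE),
               "too few")
})

test_that("the long report table stacks one row per variable and term", {
  set.seed(6)
  n <- 80
  age <- runif(n, 18, 88); grp <- rbinom(n, 1, 0.4)
  dvs <- data.frame(a = rnorm(n), b = rnorm(n))
  tab <- genotype_report(dvs, age, grp, bf_terms = character(0))
  expect_identical(nrow(tab), 12L)
  expect_identical(unique(tab$dependent_variable), c("a", "b"))
  # degenerate columns are skipped only when asked
  dvs$c <- NA_real_
  expect_error(genotype_report(dvs, age, grp, bf_terms = character(0)))
  tab2 <- suppressWarnings(
    genotype_report(dvs, age, grp, skip_degenerate = TRUE,
                    bf_terms = character(0)))
  expect_identical(attr(tab2, "skipped"), "c")
  expect_identical(nrow(tab2), 12L)
})
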
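bv_fix <- build_transition_vector(c(30, 120, 250), 2.47, 193)

test_that("window-mean contrast handles the degenerate and unit cases", {
  expect_identical(boundary_univariate_response(rep(3.2, 193), bv_fix), 0)
  expect_identical(
    boundary_univariate_response(as.numeric(bv_fix$indicator), bv_fix), 1)
  expect_error(boundary_univariate_response(rnorm(193), rep(0L, 193)),
               "degenerate")
  # linearity in the input series
  set.seed(1)
  x <- rnorm(193); y <- rnorm(193)
  expect_equal(boundary_univariate_response(2 * x + 3 * y, bv_fix),
               2 * boundary_univariate_response(x, bv_fix) +
                 3 * boundary_univariate_response(y, bv_fix))
})

test_that("the HRF-GLM estimator recovers an injected convolved response", {
  set.seed(2)
  reg <- eventconn:::hrf_convolve_regressor(as.numeric(bv_fix$indicator), 2.47)
  x <- 0.7 * reg + rnorm(193, sd = 0.01)
  est <- boundary_univariate_response(x, bv_fix, estimator = "hrf-glm-beta")
  expect_equal(est, 0.7, tolerance = 0.01)
})

test_that("PPI interaction beta is null-consistent and symmetric", {
  set.seed(3)
  n <- 5000
  ind <- integer(n); ind[sample(n, 300)] <- 1L
  z1 <- rnorm(n); z2 <- rnorm(n)
  b <- ppi_coactivation(z1, z2, ind)
  expect_lt(abs(as.numeric(b)), 3 * attr(b, "se"))
  # symmetry under argument swap, invariance to additive constants
  b_swap <- ppi_coactivation(z2, z1, ind)
  expect_equal(as.numeric(b), as.numeric(b_swap))
  b_shift <- ppi_coactivation(z1 + 100, z2 - 3, ind)
  expect_equal(as.numeric(b), as.numeric(b_shift), tolerance = 1e-8)
})

test_that("PPI beta matches a brute-force grid-search MLE", {
  set.seed(4)
  n <- 5000
  ind <- integer(n)
  ind[as.vector(outer(0:3, seq(10, n - 4, by = 45), "+"))] <- 1L
  rho <- ifelse(ind == 1, 0.8, 0)
  f <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
  z1 <- sqrt(rho) * f + sqrt(1 - rho) * e1
  z2 <- sqrt(rho) * f + sqrt(1 - rho) * e2
  b <- ppi_coactivation(z1, z2, ind)
  expect_gt(as.numeric(b), 0)
  x1 <- (z1 - mean(z1)) / sd(z1); x2 <- (z2 - mean(z2)) / sd(z2)
  X <- cbind(1, x1, x2, x1 * x2)
  oracle <- grid_search_logistic_mle(X, ind)
  expect_equal(as.numeric(b), oracle[4], tolerance = 1e-3)
})

test_that("separation triggers the penalised fallback with a flag", {
  n <- 400
  z1 <- c(rep(3, 40), rnorm(n - 40, -1, 0.1))
  z2 <- c(rep(3, 40), rnorm(n - 40, -1, 0.1))
  ind <- c(rep(1L, 40), rep(0L, n - 40))  # perfectly separable
  b <- ppi_coactivation(z1, z2, ind)
  expect_true(isTRUE(attr(b, "penalized")))
  expect_true(is.finite(as.numeric(b)))
})

test_that("the coactivation matrix is symmetric with one fit per pair", {
  set.seed(5)
  ts2 <- matrix(rnorm(193 * 2), 193, 2, dimnames = list(NULL, c("a", "b")))
  m2 <- coactivation_matrix(ts2, bv_fix)
  expect_true(is.na(m2[1, 1]) && is.na(m2[2, 2]))
  expect_identical(m2[1, 2], m2[2, 1])
  expect_equal(m2[1, 2], as.numeric(ppi_coactivation(ts2[, 1], ts2[, 2], bv_fix)))

  ts5 <- matrix(rnorm(193 * 5), 193, 5,
                dimnames = list(NULL, paste0("r", 1:5)))
  m5 <- coactivation_matrix(ts5, bv_fix)
  expect_identical(sum(!is.na(m5[upper.tri(m5)])), 10L)  # R(R-1)/2 fits
  expect_identical(unclass(m5), t(unclass(m5)))
})

test_that("permuting ROI order permutes the matrix consistently", {
  set.seed(6)
  ts <- matrix(rnorm(193 * 4), 193, 4, dimnames = list(NULL, paste0("r", 1:4)))
  m <- coactivation_matrix(ts, bv_fix)
  perm <- c(3, 1, 4, 2)
  m_perm <- coactivation_matrix(ts[, perm], bv_fix)
  expect_equal(unclass(m_perm), unclass(m)[perm, perm], ignore_attr = TRUE)
})

test_that("all-positive cluster selection matches exhaustive enumeration", {
  labs <- c(paste0("p", 1:5), "hipp")
  set.seed(7)
  M <- matrix(abs(rnorm(36, 0.3, 0.1)), 6, 6, dimnames = list(labs, labs))
  M <- (M + t(M)) / 2; diag(M) <- NA
  M["p4", c("p1", "p2")] <- M[c("p1", "p2"), "p4"] <- -0.05  # spoiler parcel
  got <- select_coactive_cluster(M, list(dmn = paste0("p", 1:5)),
                                 hippocampus = "hipp")
  # oracle: enumerate all 2^5 subsets directly
  all_pos <- function(sub) {
    ok <- TRUE
    if (length(sub) > 1) {
      for (pair in utils::combn(sub, 2, simplify = FALSE)) {
        ok <- ok && M[pair[1], pair[2]] > 0
      }
    }
    ok && all(M[sub, "hipp"] > 0)
  }
  best <- character(0)
  for (size in 5:1) {
    cands <- utils::combn(paste0("p", 1:5), size, simplify = FALSE)
    ok <- Filter(all_pos, cands)
    if (length(ok)) {
      sums <- vapply(ok, function(s) sum(M[s, s][upper.tri(M[s, s])],
                                         M[s, "hipp"]), numeric(1))
      best <- ok[[which.max(sums)]]
      break
    }
  }
  expect_setequal(got$dmn, best)
  expect_false("p4" %in% got$dmn)
  # self-consistency: the output always passes its own predicate
  expect_true(eventconn:::all_positive_cluster(M, got$dmn, "hipp"))
})

test_that("cluster selection covers saturated, empty and failing cases", {
  labs <- paste0("p", 1:4)
  M <- matrix(0.2, 4, 4, dimnames = list(labs, labs)); diag(M) <- NA
  expect_setequal(select_coactive_cluster(M, list(labs))[[1]], labs)
  expect_identical(select_coactive_cluster(M, list()), list())
  Mneg <- -M
  expect_warning(out <- select_coactive_cluster(Mneg, list(x = labs)),
                 "no all-positive")
  expect_identical(out$x, character(0))
})

test_that("ROI merging averages member series per volume", {
  ts <- cbind(a = c(1, 4), b = c(2, 5), c = c(3, 6))
  merged <- merge_rois(ts, list(abc = c("a", "b", "c"), solo = "b"))
  expect_equal(unname(merged[, "abc"]), c(2, 5))
  expect_equal(unname(merged[, "solo"]), unname(ts[, "b"]))
  dup <- merge_rois(cbind(a = c(1, 2), b = c(1, 2)), list(m = c("a", "b")))
  expect_equal(unname(dup[, "m"]), c(1, 2))
  expect_error(merge_rois(ts, list(bad = c("a", "zz"))), "zz")
})
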
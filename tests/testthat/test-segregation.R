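test_that("global signal regression is an orthogonal projection", {
  # a single ROI is annihilated (it equals its own global mean)
  x1 <- matrix(rnorm(100), 100, 1)
  expect_lt(max(abs(global_signal_regress(x1))), 1e-10)
  # residuals orthogonal to the global mean for random input
  set.seed(1)
  ts <- matrix(rnorm(200 * 5), 200, 5)
  res <- global_signal_regress(ts)
  gs <- rowMeans(ts)
  expect_lt(max(abs(crossprod(gs, res))) /
              (sqrt(sum(gs^2)) * max(sqrt(colSums(res^2)))), 1e-8)
  # 2-ROI toy against hand-written normal equations
  ts2 <- cbind(c(1, 2, 3, 5), c(0, 1, 1, 2))
  g <- rowMeans(ts2)
  X <- cbind(1, g)
  oracle <- ts2 - X %*% solve(t(X) %*% X, t(X) %*% ts2)
  expect_equal(global_signal_regress(ts2), oracle, tolerance = 1e-10)
})

test_that("connectivity matrices follow the correlation definition", {
  set.seed(2)
  x <- rnorm(50)
  ts <- cbind(a = x, b = x, c = rnorm(50))
  C <- connectivity_matrix(ts)
  expect_equal(C["a", "b"], 1)
  expect_identical(diag(C), c(a = 1, b = 1, c = 1))
  # orthogonal mean-zero series correlate to zero
  u <- c(1, -1, 1, -1); v <- c(1, 1, -1, -1)
  expect_equal(connectivity_matrix(cbind(u, v, w = rnorm(4)))["u", "v"], 0)
  # random 5-ROI input against the covariance formula
  ts5 <- matrix(rnorm(60 * 5), 60, 5)
  Cc <- connectivity_matrix(ts5)
  oracle <- crossprod(scale(ts5, TRUE, FALSE)) / 59
  oracle <- oracle / tcrossprod(sqrt(diag(oracle)))
  expect_equal(unname(Cc), unname(oracle), tolerance = 1e-12)
  # zero-variance ROI propagates NA with a warning
  expect_warning(Cz <- connectivity_matrix(cbind(k = rep(1, 50), r = rnorm(50))),
                 "zero-variance")
  expect_true(is.na(Cz["k", "r"]))
})

part6 <- c(r1 = "A", r2 = "A", r3 = "A", r4 = "B", r5 = "B", r6 = "B")

block_matrix <- function(within, between) {
  M <- matrix(between, 6, 6, dimnames = list(names(part6), names(part6)))
  M[1:3, 1:3] <- within; M[4:6, 4:6] <- within
  diag(M) <- 1
  M
}

test_that("system segregation reproduces its closed-form cases", {
  # perfect segregation: positive within, zero between
  s1 <- system_segregation(block_matrix(0.5, 0), part6)
  expect_equal(s1$sys, 1, tolerance = 1e-12)
  # uniform connectivity: no segregation
  s0 <- system_segregation(block_matrix(0.4, 0.4), part6)
  expect_equal(s0$sys, 0, tolerance = 1e-12)
  # the 0.6 / 0.3 toy
  s <- system_segregation(block_matrix(0.6, 0.3), part6)
  expect_equal(s$mean_within, 0.6, tolerance = 1e-12)
  expect_equal(s$mean_between, 0.3, tolerance = 1e-12)
  expect_equal(s$sys, 0.5, tolerance = 1e-12)
})

test_that("SyS is invariant to permuting ROIs within networks", {
  set.seed(3)
  M <- block_matrix(0.5, 0.1) + matrix(rnorm(36, 0, 0.01), 6, 6)
  M <- (M + t(M)) / 2; diag(M) <- 1
  perm <- c(3, 1, 2, 6, 4, 5)  # permutes within each network
  Mp <- M[perm, perm]
  s <- system_segregation(M, part6)
  sp <- system_segregation(Mp, part6)
  expect_equal(sp$sys, s$sys, tolerance = 1e-12)
})

test_that("non-positive within-network connectivity flags SyS undefined", {
  expect_warning(s <- system_segregation(block_matrix(-0.2, 0.1), part6),
                 "undefined")
  expect_false(s$defined)
  expect_true(is.na(s$sys))
  expect_error(system_segregation(block_matrix(0.5, 0.1),
                                  c(part6[-6], r6 = "C")), "within-network")
})

test_that("averaging options and partition files behave", {
  M <- block_matrix(0.6, 0.3)
  sz <- system_segregation(M, part6, fisher_z = TRUE)
  expect_gt(sz$sys, 0)  # same ordering under z-averaging
  sn <- system_segregation(block_matrix(0.5, -0.2), part6,
                           drop_negative = TRUE)
  expect_equal(sn$mean_between, 0, tolerance = 1e-12)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "part.csv")
  utils::write.csv(data.frame(roi_label = names(part6),
                              network_label = part6), f, row.names = FALSE)
  expect_identical(read_partition(f), part6)
})

test_that("estimated SyS increases with the generative modularity gap", {
  sys_at <- function(w) {
    mean(vapply(1:8, function(r) {
      cfg <- sim_config(n_subjects = 1, n_rois = 8, n_vols = 400,
                        boundary_amplitude = 0, confound_weight = 0,
                        baseline_rho = 0.1, boundary_coact_rho = 0.1,
                        within_network_rho = w, noise_ar1 = 0,
                        seed = 7000 + r)
      s <- generate_roi_timeseries(generate_cohort(cfg)[1, ], cfg)
      system_segregation(connectivity_matrix(s$ts),
                         sim_network_partition(cfg))$sys
    }, numeric(1)))
  }
  curve <- c(sys_at(0.1), sys_at(0.3), sys_at(0.5))
  expect_true(all(diff(curve) > 0))
})
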
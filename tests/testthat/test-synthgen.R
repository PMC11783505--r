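test_that("cohort generation honours the empty case and is deterministic", {
  cfg <- quick_sim(n_subjects = 0)
  expect_identical(nrow(generate_cohort(cfg)), 0L)

  cfg <- quick_sim(n_subjects = 50, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  s1 <- generate_roi_timeseries(generate_cohort(cfg)[1, ], cfg)
  s2 <- generate_roi_timeseries(generate_cohort(cfg)[1, ], cfg)
  expect_identical(s1, s2)

  d1 <- generate_dataset(quick_sim(n_subjects = 3))
  d2 <- generate_dataset(quick_sim(n_subjects = 3))
  expect_identical(d1, d2)
})

test_that("genotype draws match the configured frequencies", {
  freqs <- c("e3/e3" = 0.6, "e3/e4" = 0.3, "e4/e4" = 0.02, "e2-carrier" = 0.08)
  n <- 4000
  cohort <- generate_cohort(sim_config(n_subjects = n, genotype_freqs = freqs,
                                       seed = 2024))
  for (g in names(freqs)) {
    p <- freqs[[g]]
    tol <- 3 * sqrt(p * (1 - p) / n)  # three binomial SDs
    expect_lt(abs(mean(cohort$genotype == g) - p), tol)
  }
  expect_false(any(duplicated(cohort$subject_id)))
  expect_true(all(cohort$age >= 18 & cohort$age <= 88))
})

test_that("misconfigured genotype frequencies are rejected", {
  expect_error(sim_config(genotype_freqs = c("e3/e3" = 0.6, "e3/e4" = 0.3,
                                             "e4/e4" = 0.02, "e2-carrier" = 0.3)),
               "sum to 1")
  expect_error(sim_config(noise_ar1 = 1), "noise_ar1")
  expect_error(sim_config(boundary_onsets_s = c(30, 1e5)), "onsets")
})

test_that("noiseless observers mark exactly the true onsets", {
  true <- c(30, 72, 105)
  ann <- generate_observer_annotations(true, n_observers = 5, miss_rate = 0,
                                       jitter_sd = 0, seed = 1)
  expect_identical(nrow(ann), 15L)
  for (o in 1:5) {
    expect_equal(sort(ann$onset_s[ann$observer_id == o]), true)
  }
  expect_error(generate_observer_annotations(true, jitter_sd = -1), "jitter_sd")
})

test_that("consensus recovers the true boundaries under 20% misses", {
  # Monte-Carlo oracle on the binomial tail: with 16 observers each hitting a
  # boundary w.p. 0.8, P(>= 8 observers) is ~0.999 per boundary, so the full
  # 12-boundary set should be recovered in well over 95% of replicates.
  true <- sim_config()$boundary_onsets_s
  hits <- vapply(1:500, function(r) {
    ann <- generate_observer_annotations(true, n_observers = 16,
                                         miss_rate = 0.2, jitter_sd = 0.3,
                                         seed = 9000 + r)
    got <- consensus_boundaries(ann, n_observers = 16, threshold = 0.5)
    length(got) == length(true) && max(abs(got - true)) < 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("zero-signal, zero-noise configuration yields constant series", {
  cfg <- silent_sim(n_subjects = 1, n_rois = 3)
  s <- generate_roi_timeseries(generate_cohort(cfg)[1, ], cfg)
  expect_true(all(s$ts == 0))
  expect_identical(dim(s$ts), c(193L, 3L))
  expect_identical(dim(s$confounds), c(193L, 8L))
})

test_that("pure-noise output reproduces the configured AR(1) coefficient", {
  cfg <- sim_config(n_subjects = 1, n_rois = 2, n_vols = 5000,
                    boundary_amplitude = 0, confound_weight = 0,
                    baseline_rho = 0, boundary_coact_rho = 0,
                    within_network_rho = 0, noise_ar1 = 0.4, seed = 31)
  s <- generate_roi_timeseries(generate_cohort(cfg)[1, ], cfg)
  for (j in 1:2) {
    r1 <- stats::acf(s$ts[, j], lag.max = 1, plot = FALSE)$acf[2]
    expect_lt(abs(r1 - 0.4), 0.05)
  }
})

test_that("injected boundary amplitude is recovered by the window contrast", {
  # round-trip recovery: 100 subjects, amplitude 0.5, unit white noise; the
  # cohort-mean univariate response should sit inside its simulation 95% CI
  # around the injected amplitude
  cfg <- sim_config(n_subjects = 100, n_rois = 2, boundary_amplitude = 0.5,
                    noise_sd = 1, noise_ar1 = 0, confound_weight = 0,
                    age_slope_linear = 0, age_slope_quadratic = 0,
                    genotype_effect = 0, seed = 77)
  d <- generate_dataset(cfg)
  est <- vapply(d$subjects, function(s) {
    boundary_univariate_response(s$ts[, 1], s$bvec)
  }, numeric(1))
  ci_half <- 1.96 * stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), ci_half + 1e-12)
})

test_that("injected boundary coactivation yields positive PPI betas", {
  # Monte-Carlo sign oracle: rho 0.8 at transitions vs 0.0 within events
  pos <- vapply(1:60, function(r) {
    cfg <- sim_config(n_subjects = 1, n_rois = 2, n_vols = 965,
                      boundary_amplitude = 0, confound_weight = 0,
                      boundary_coact_rho = 0.8, baseline_rho = 0,
                      within_network_rho = 0, noise_ar1 = 0,
                      boundary_onsets_s = seq(30, 2300, by = 47),
                      seed = 500 + r)
    s <- generate_roi_timeseries(generate_cohort(cfg)[1, ], cfg)
    as.numeric(ppi_coactivation(s$ts[, 1], s$ts[, 2], s$bvec)) > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})

test_that("datasets round-trip to disk in plain-text form", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(quick_sim(n_subjects = 2, n_rois = 3))
  write_dataset(d, dir)
  cohort <- utils::read.delim(file.path(dir, "cohort.tsv"))
  expect_identical(nrow(cohort), 2L)
  ts <- utils::read.csv(file.path(dir, "sub-0001_roi.csv"))
  expect_identical(dim(ts), c(193L, 3L))
  expect_equal(as.matrix(ts), d$subjects[["sub-0001"]]$ts,
               ignore_attr = TRUE, tolerance = 1e-6)
})
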
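#' Simulation configuration for a movie-watching imaging-genetics cohort
#'
#' Bundles every parameter of the synthetic cohort, annotation and ROI
#' time-series generators. The defaults emulate the design the package
#' targets: 193 volumes at TR = 2.47 s (an ~8-minute movie scan), a cohort
#' of 425 adults aged 18-88, APOE genotype frequencies matching a genotyped
#' population sample in which epsilon-2 carriers are later excluded, twelve
#' consensus event boundaries, boundary-locked activation and default-mode
#' coactivation increases, age-related decline of the boundary response, and
#' a genotype effect of zero (the null the design interrogates).
#'
#' @param n_subjects cohort size before genotype exclusions.
#' @param age_range ages are drawn uniformly over this range (years).
#' @param genotype_freqs named proportions over
#'   `c("e3/e3","e3/e4","e4/e4","e2-carrier")`; must sum to 1 (tolerance
#'   1e-9).
#' @param n_vols,tr_s scan length in volumes and repetition time in seconds.
#' @param n_rois number of ROI-averaged signals per subject.
#' @param boundary_onsets_s consensus event-boundary onsets in seconds; all
#'   must lie in `[0, n_vols * tr_s)`.
#' @param boundary_amplitude boundary-locked BOLD response amplitude, in
#'   units of the noise SD, injected in every ROI.
#' @param boundary_coact_rho,baseline_rho pairwise correlation injected
#'   between the `coact_rois` at transition vs within-event timepoints.
#' @param within_network_rho extra correlation shared within each of two
#'   contiguous, equal-size ROI networks (see [sim_network_partition()]),
#'   layered under the boundary coactivation; gives the modular structure
#'   that the system-segregation analysis presumes.
#' @param coact_rois integer indices of the ROIs sharing the common
#'   coactivation factor; defaults to all ROIs.
#' @param age_slope_linear,age_slope_quadratic multiplicative modulation of
#'   the boundary amplitude per SD of age (linear and quadratic terms).
#' @param genotype_effect additive boundary-amplitude shift for the e4+
#'   group, in noise-SD units; 0 reproduces the null design.
#' @param noise_sd SD of the ROI noise innovations (signal units).
#' @param noise_ar1 lag-1 autocorrelation of the ROI noise, in `[0, 1)`.
#' @param confound_weight maximum absolute mixing weight of each confound
#'   source into an ROI, as a fraction of `noise_sd` (kept modest so
#'   nuisance cleaning is measurable but not dominant).
#' @param hrf_convolve if `TRUE` the injected boundary response is the
#'   transition boxcar convolved with a canonical double-gamma HRF instead
#'   of the raw boxcar.
#' @param window_tr,lag_tr transition-window geometry used to place the
#'   injected response (matches [build_transition_vector()]).
#' @param seed base RNG seed for the whole simulation.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 425,
                       age_range = c(18, 88),
                       genotype_freqs = c("e3/e3" = 0.583, "e3/e4" = 0.253,
                                          "e4/e4" = 0.016, "e2-carrier" = 0.148),
                       n_vols = 193,
                       tr_s = 2.47,
                       n_rois = 15,
                       boundary_onsets_s = c(30, 72, 105, 150, 186, 222,
                                             260, 299, 333, 370, 407, 446),
                       boundary_amplitude = 0.5,
                       boundary_coact_rho = 0.3,
                       baseline_rho = 0.1,
                       within_network_rho = 0.3,
                       coact_rois = NULL,
                       age_slope_linear = -0.2,
                       age_slope_quadratic = -0.1,
                       genotype_effect = 0,
                       noise_sd = 1,
                       noise_ar1 = 0.3,
                       confound_weight = 0.2,
                       hrf_convolve = FALSE,
                       window_tr = 2,
                       lag_tr = 2,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, age_range = age_range,
              genotype_freqs = genotype_freqs, n_vols = n_vols, tr_s = tr_s,
              n_rois = n_rois, boundary_onsets_s = boundary_onsets_s,
              boundary_amplitude = boundary_amplitude,
              boundary_coact_rho = boundary_coact_rho,
              baseline_rho = baseline_rho,
              within_network_rho = within_network_rho,
              coact_rois = if (is.null(coact_rois)) seq_len(n_rois) else coact_rois,
              age_slope_linear = age_slope_linear,
              age_slope_quadratic = age_slope_quadratic,
              genotype_effect = genotype_effect, noise_sd = noise_sd,
              noise_ar1 = noise_ar1, confound_weight = confound_weight,
              hrf_convolve = hrf_convolve, window_tr = window_tr,
              lag_tr = lag_tr, seed = seed)
  validate_sim_config(cfg)
}

GENOTYPE_LEVELS <- c("e3/e3", "e3/e4", "e4/e4", "e2-carrier")

validate_sim_config <- function(cfg) {
  stopifnot_scalar(cfg$n_subjects, "n_subjects", lower = 0)
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) < 0) {
    stop("`age_range` must be c(min, max) with min <= max", call. = FALSE)
  }
  f <- cfg$genotype_freqs
  if (!setequal(names(f), GENOTYPE_LEVELS)) {
    stop("`genotype_freqs` must be named over ",
         paste(GENOTYPE_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    stop("`genotype_freqs` must be nonnegative and sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  stopifnot_scalar(cfg$n_vols, "n_vols", lower = 1)
  stopifnot_scalar(cfg$tr_s, "tr_s", lower = 1e-12)
  stopifnot_scalar(cfg$n_rois, "n_rois", lower = 1)
  stopifnot_scalar(cfg$noise_ar1, "noise_ar1", lower = 0, upper = 1 - 1e-12)
  stopifnot_scalar(cfg$noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar(cfg$boundary_coact_rho, "boundary_coact_rho", -1, 1)
  stopifnot_scalar(cfg$baseline_rho, "baseline_rho", -1, 1)
  stopifnot_scalar(cfg$within_network_rho, "within_network_rho", 0, 1)
  dur <- cfg$n_vols * cfg$tr_s
  if (any(cfg$boundary_onsets_s < 0 | cfg$boundary_onsets_s >= dur)) {
    stop(sprintf("all boundary onsets must lie in [0, %.2f)", dur), call. = FALSE)
  }
  if (any(!cfg$coact_rois %in% seq_len(cfg$n_rois))) {
    stop("`coact_rois` must index ROIs 1..n_rois", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("Simulation config: %d subjects aged %g-%g, %d ROIs x %d volumes ",
           "(TR %.2f s)\n  %d boundaries; amplitude %.2f, coact rho %.2f/%.2f, ",
           "genotype effect %.2f, AR(1) %.2f, seed %d\n"),
    x$n_subjects, x$age_range[1], x$age_range[2], x$n_rois, x$n_vols, x$tr_s,
    length(x$boundary_onsets_s), x$boundary_amplitude, x$boundary_coact_rho,
    x$baseline_rho, x$genotype_effect, x$noise_ar1, as.integer(x$seed)))
  invisible(x)
}

#' Generate a synthetic cohort table
#'
#' Draws `n_subjects` subjects with ages uniform over the configured range
#' and genotypes from the configured frequencies. A small epsilon-2 carrier
#' frequency is kept in the defaults so the downstream exclusion path is
#' exercised.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `subject_id`, `age`, `genotype`,
#'   `included`.
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  n <- as.integer(config$n_subjects)
  with_seed(config$seed, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    genotype <- if (n > 0) {
      sample(names(config$genotype_freqs), n, replace = TRUE,
             prob = config$genotype_freqs)
    } else character(0)
    data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
               age = age, genotype = genotype, included = rep(TRUE, n),
               stringsAsFactors = FALSE)
  })
}

#' Simulate observer boundary annotations
#'
#' Emulates the behavioural segmentation experiment: each of `n_observers`
#' watches the movie and marks each true boundary with probability
#' `1 - miss_rate`, at a time jittered by Gaussian noise of SD `jitter_sd`
#' seconds and clipped to the scan duration.
#'
#' @param true_onsets true boundary onsets in seconds.
#' @param n_observers number of observers (default 16, the annotator count of
#'   the emulated design).
#' @param miss_rate per-observer, per-boundary miss probability.
#' @param jitter_sd SD of the annotation-time jitter in seconds (>= 0).
#' @param duration_s scan duration used for clipping.
#' @param seed RNG seed.
#' @return data frame with columns `observer_id`, `onset_s` and attribute
#'   `n_observers`.
#' @export
generate_observer_annotations <- function(true_onsets, n_observers = 16,
                                          miss_rate = 0, jitter_sd = 0,
                                          duration_s = 193 * 2.47, seed = NULL) {
  stopifnot_scalar(n_observers, "n_observers", lower = 1)
  stopifnot_scalar(miss_rate, "miss_rate", lower = 0, upper = 1)
  if (!is.numeric(jitter_sd) || jitter_sd < 0) {
    stop("`jitter_sd` must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    recs <- lapply(seq_len(n_observers), function(o) {
      hit <- stats::runif(length(true_onsets)) >= miss_rate
      t <- true_onsets[hit]
      if (length(t)) t <- t + stats::rnorm(length(t), 0, jitter_sd)
      data.frame(observer_id = rep.int(o, length(t)),
                 onset_s = pmin(pmax(t, 0), duration_s))
    })
    ann <- do.call(rbind, recs)
    attr(ann, "n_observers") <- as.integer(n_observers)
    ann
  })
}

# Canonical double-gamma HRF sampled at TR resolution (SPM-style shape:
# peak 6 s, undershoot 16 s, ratio 1/6), normalised to unit peak.
canonical_hrf <- function(tr_s, len_s = 32) {
  t <- seq(0, len_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Convolve a per-volume regressor with the canonical HRF (causal, truncated).
hrf_convolve_regressor <- function(x, tr_s) {
  h <- canonical_hrf(tr_s)
  y <- stats::convolve(x, rev(h), type = "open")[seq_along(x)]
  y
}

#' Simulate one subject's ROI time series and confound sources
#'
#' The generative model, per ROI: a boundary-locked response (a boxcar over
#' the lag-shifted transition window, or its HRF convolution) with amplitude
#' `boundary_amplitude * (1 + b1 * z_age + b2 * z_age^2) + genotype_effect`
#' for e4 carriers; plus AR(1) noise whose innovations share a common factor
#' across the designated ROIs, giving pairwise correlation
#' `boundary_coact_rho` at transition timepoints and `baseline_rho` within
#' events; plus small mixtures of eight generated confound sources (six
#' motion parameters and WM/CSF means, smoothed Gaussian random walks).
#' Age is standardised against the configured uniform age distribution, so
#' the slopes are per population SD of age.
#'
#' @param subject one row of a [generate_cohort()] table (or a list with
#'   `age` and `genotype`).
#' @param config a [sim_config()].
#' @param boundaries boundary onsets in seconds; defaults to
#'   `config$boundary_onsets_s`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with `ts` (volumes x ROIs matrix, columns `roi_01`, ...),
#'   `confounds` (volumes x 8 matrix: `mot_1`..`mot_6`, `wm`, `csf`),
#'   `tr_s`, and `bvec` (the transition `boundary_vector` used for
#'   injection).
#' @export
generate_roi_timeseries <- function(subject, config,
                                    boundaries = config$boundary_onsets_s,
                                    seed = config$seed) {
  config <- validate_sim_config(config)
  n <- as.integer(config$n_vols); R <- as.integer(config$n_rois)
  bvec <- build_transition_vector(boundaries, config$tr_s, n,
                                  window_tr = config$window_tr,
                                  lag_tr = config$lag_tr)
  reg <- as.numeric(bvec$indicator)
  if (config$hrf_convolve) reg <- hrf_convolve_regressor(reg, config$tr_s)

  age_mu <- mean(config$age_range)
  age_sd <- diff(config$age_range) / sqrt(12)  # SD of the uniform age law
  za <- if (age_sd > 0) (subject$age - age_mu) / age_sd else 0
  amp <- config$boundary_amplitude *
    (1 + config$age_slope_linear * za + config$age_slope_quadratic * za^2)
  if (subject$genotype %in% c("e3/e4", "e4/e4")) {
    amp <- amp + config$genotype_effect
  }

  with_seed(seed, {
    # innovations, layered: (1) idiosyncratic noise; (2) a per-network
    # factor giving modular within-network correlation; (3) a common factor
    # over the designated ROIs whose share is rho_t (time-varying:
    # boundary_coact_rho during transitions, baseline_rho within events)
    rho_t <- ifelse(bvec$indicator == 1, config$boundary_coact_rho,
                    config$baseline_rho)
    rho_t <- pmax(rho_t, 0)
    f <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * R), n, R)
    net <- sim_network_index(R)
    h <- matrix(stats::rnorm(n * max(net)), n, max(net))
    w <- config$within_network_rho
    innov <- sqrt(w) * h[, net, drop = FALSE] + sqrt(1 - w) * eps
    idx <- config$coact_rois
    innov[, idx] <- sqrt(rho_t) * f + sqrt(1 - rho_t) * innov[, idx]
    # AR(1) filtering per ROI; innovations scaled to keep marginal SD noise_sd
    phi <- config$noise_ar1
    scale <- config$noise_sd * sqrt(1 - phi^2)
    noise <- apply(innov * scale, 2, function(e) {
      as.numeric(stats::filter(e, phi, method = "recursive"))
    })
    noise <- matrix(noise, n, R)

    confounds <- generate_confound_sources(n)
    mix <- matrix(stats::runif(8 * R, -1, 1) * config$confound_weight *
                    config$noise_sd, 8, R)

    ts <- amp * reg + noise + confounds %*% mix
    colnames(ts) <- sprintf("roi_%02d", seq_len(R))
    list(ts = ts, confounds = confounds, tr_s = config$tr_s, bvec = bvec)
  })
}

sim_network_index <- function(n_rois) {
  rep(1:2, c(ceiling(n_rois / 2), floor(n_rois / 2)))[seq_len(n_rois)]
}

#' Network partition implied by a simulation config
#'
#' The generator gives the first half of the ROIs (rounded up) one shared
#' network factor and the second half another; this returns that partition
#' in the named-vector form [system_segregation()] expects.
#'
#' @param config a [sim_config()].
#' @return named character vector `roi label -> "net_A"/"net_B"`.
#' @export
sim_network_partition <- function(config) {
  R <- as.integer(config$n_rois)
  stats::setNames(c("net_A", "net_B")[sim_network_index(R)],
                  sprintf("roi_%02d", seq_len(R)))
}

# Eight confound sources (6 motion, WM, CSF) as smoothed Gaussian random
# walks, each standardised to mean 0 / SD 1 over the scan.
generate_confound_sources <- function(n_vols) {
  src <- vapply(1:8, function(i) {
    w <- cumsum(stats::rnorm(n_vols))
    sm <- stats::filter(w, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- w[is.na(sm)]
    zscore(as.numeric(sm))
  }, numeric(n_vols))
  colnames(src) <- c(sprintf("mot_%d", 1:6), "wm", "csf")
  src
}

#' Simulate a whole cohort dataset
#'
#' Convenience wrapper: generates the cohort table and, for each subject, the
#' ROI time series and confound sources. Per-subject seeds are derived from
#' `config$seed` so the whole dataset is reproducible.
#'
#' @param config a [sim_config()].
#' @return list with `cohort`, `subjects` (named list of
#'   [generate_roi_timeseries()] outputs), and `config`.
#' @export
generate_dataset <- function(config) {
  config <- validate_sim_config(config)
  cohort <- generate_cohort(config)
  subjects <- lapply(seq_len(nrow(cohort)), function(i) {
    generate_roi_timeseries(cohort[i, ], config,
                            seed = config$seed + 1000L + i)
  })
  names(subjects) <- cohort$subject_id
  list(cohort = cohort, subjects = subjects, config = config)
}

#' Write simulated data to disk
#'
#' Writes the cohort as TSV (`subject_id`, `age`, `genotype`), each subject's
#' ROI series and confounds as CSV with header rows, using 0-based volume
#' indexing in file row order.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$cohort[c("subject_id", "age", "genotype")],
                     file.path(dir, "cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (id in names(dataset$subjects)) {
    s <- dataset$subjects[[id]]
    utils::write.csv(as.data.frame(s$ts),
                     file.path(dir, paste0(id, "_roi.csv")), row.names = FALSE)
    utils::write.csv(as.data.frame(s$confounds),
                     file.path(dir, paste0(id, "_confounds.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
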
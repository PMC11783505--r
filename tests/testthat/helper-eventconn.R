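# Shared fixtures: all synthetic, built in code at test time.

# A small, fast cohort configuration for pipeline-level tests.
quick_sim <- function(n_subjects = 40, n_rois = 4, seed = 11, ...) {
  sim_config(n_subjects = n_subjects, n_rois = n_rois, seed = seed, ...)
}

# Noise-free, signal-free configuration: every series should be constant.
silent_sim <- function(...) {
  sim_config(boundary_amplitude = 0, noise_sd = 0, confound_weight = 0,
             genotype_effect = 0, ...)
}

# Annotations where observers `obs` all click at `onset`.
clicks_at <- function(onset, obs) {
  data.frame(observer_id = obs, onset_s = rep(onset, length(obs)))
}

# Independent log-likelihood for the PPI logistic model (used by oracles).
logistic_loglik <- function(X, y, beta) {
  eta <- as.numeric(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Brute-force logistic MLE by cyclic coordinate search over shrinking grids;
# independent of the IRLS path used by the package.
grid_search_logistic_mle <- function(X, y, sweeps = 80, init_delta = 2) {
  beta <- numeric(ncol(X))
  delta <- init_delta
  for (s in seq_len(sweeps)) {
    for (j in seq_along(beta)) {
      cand <- beta[j] + seq(-delta, delta, length.out = 21)
      ll <- vapply(cand, function(b) {
        bb <- beta; bb[j] <- b
        logistic_loglik(X, y, bb)
      }, numeric(1))
      beta[j] <- cand[which.max(ll)]
    }
    delta <- delta * 0.75
  }
  beta
}

# Independent oracle: marginal likelihood ratio of a p-covariate regression
# to the intercept-only model under the Zellner-Siow prior, evaluated from
# projection matrices and a trapezoid rule over a log-spaced g grid (no
# shared code with the package's R^2-formula + adaptive-quadrature path).
oracle_jzs_bf <- function(y, Xc, r = sqrt(2) / 2) {
  n <- length(y); p <- ncol(Xc)
  yc <- y - mean(y)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  P <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  a <- n * r^2 / 2
  g <- exp(seq(log(1e-6), log(1e8), length.out = 6000))
  log_ratio <- vapply(g, function(gv) {
    M <- diag(n) + gv * P
    q <- as.numeric(yc %*% solve(M, yc))
    as.numeric(-0.5 * determinant(M)$modulus - (n - 1) / 2 * log(q) +
                 (n - 1) / 2 * log(sum(yc^2)))
  }, numeric(1))
  log_prior <- 0.5 * log(a) - lgamma(0.5) - 1.5 * log(g) - a / g
  f <- exp(log_ratio + log_prior)
  sum(diff(g) * (f[-1] + f[-length(f)]) / 2)  # BF(model vs null)
}
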
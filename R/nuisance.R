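#' Build the 32-column confound design
#'
#' Expands the eight confound sources — six rigid-body motion parameters plus
#' the timepoint-by-timepoint white-matter and CSF means — into the standard
#' 32-regressor nuisance design: the 8 base series, their temporal
#' derivatives, their squares, and the squared derivatives. Derivatives are
#' backward differences with a leading 0 (SPM convention).
#'
#' @param motion volumes x 6 matrix of motion parameters.
#' @param wm,csf white-matter and CSF mean series (same length as `motion`
#'   rows).
#' @return volumes x 32 matrix with labelled columns (`<name>`,
#'   `<name>_d`, `<name>_sq`, `<name>_dsq`).
#' @export
build_confound_matrix <- function(motion, wm, csf) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns", call. = FALSE)
  n <- nrow(motion)
  if (length(wm) != n || length(csf) != n) {
    stop("motion, wm and csf must have the same number of timepoints",
         call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 timepoints", call. = FALSE)
  base <- cbind(motion, wm, csf)
  nm <- colnames(base)
  if (is.null(nm) || any(nm == "")) nm <- c(sprintf("mot_%d", 1:6), "wm", "csf")
  deriv <- apply(base, 2, function(x) c(0, diff(x)))
  out <- cbind(base, deriv, base^2, deriv^2)
  colnames(out) <- c(nm, paste0(nm, "_d"), paste0(nm, "_sq"), paste0(nm, "_dsq"))
  out
}

#' Discrete cosine high-pass basis
#'
#' DCT-II cosine set implementing a high-pass filter inside the GLM: column
#' `k` has frequency `k / (2 * n_vols * tr_s)` Hz, and columns are included
#' for `k = 1..K` with `K = floor(2 * n_vols * tr_s * cutoff_hz)`, i.e. all
#' non-constant cosines at or below the cutoff. For a 193-volume scan at
#' TR = 2.47 s and the 0.008 Hz cutoff this gives 7 columns. Columns are
#' normalised to unit length and are mutually orthogonal; the constant term
#' is excluded (the model intercept carries it).
#'
#' @param n_vols number of volumes.
#' @param tr_s repetition time in seconds.
#' @param cutoff_hz high-pass cutoff frequency in Hz (>= 0; 0 gives a
#'   zero-column matrix).
#' @return `n_vols` x `K` matrix.
#' @export
dct_basis <- function(n_vols, tr_s, cutoff_hz = 0.008) {
  stopifnot_scalar(n_vols, "n_vols", lower = 1)
  stopifnot_scalar(tr_s, "tr_s", lower = 1e-12)
  stopifnot_scalar(cutoff_hz, "cutoff_hz", lower = 0)
  n <- as.integer(n_vols)
  K <- floor(2 * n * tr_s * cutoff_hz)
  K <- min(K, n - 1L)
  if (K < 1) return(matrix(numeric(0), n, 0))
  t <- seq_len(n) - 1L
  B <- vapply(seq_len(K),
              function(k) cos(pi * (2 * t + 1) * k / (2 * n)),
              numeric(n))
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  colnames(B) <- sprintf("dct_%03d", seq_len(K))
  B
}

#' Simultaneous nuisance regression and high-pass filtering
#'
#' Regresses each ROI series on `[intercept | confounds | dct]` in a single
#' least-squares fit, so that filtering and confound removal are performed
#' simultaneously rather than sequentially. Returns the residual series.
#' Collinear design columns are dropped (pivoted out by the QR
#' decomposition) with a warning.
#'
#' @param ts volumes x ROIs numeric matrix.
#' @param confounds confound design, e.g. [build_confound_matrix()]; may be
#'   `NULL`.
#' @param dct cosine basis, e.g. [dct_basis()]; may be `NULL`.
#' @return residual matrix of the same shape and column names as `ts`.
#' @export
clean_timeseries <- function(ts, confounds = NULL, dct = NULL) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  X <- cbind(intercept = rep(1, n), confounds, dct)
  if (!is.null(confounds) && nrow(as.matrix(confounds)) != n ||
      !is.null(dct) && nrow(as.matrix(dct)) != n) {
    stop("design row count does not match the time series", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf("dropping %d collinear design column(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  res <- qr.resid(qrX, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Fit the eight-exponential autocovariance model
#'
#' Models the temporal autocovariance of the GLM residuals as a nonnegative
#' mixture of eight exponential kernels with half-lives 0.5, 1, 2, 4, 8, 16,
#' 32 and 64 TRs, plus a white (delta) component. The empirical
#' autocovariance at lags `0..min(n_vols - 1, max_lag)` is fit by
#' nonnegative least squares over the basis `0.5^(lag / h)`. By default one
#' pooled model is estimated from the ROI-averaged autocovariance; set
#' `pooled = FALSE` to fit one model per ROI.
#'
#' @param residuals volumes x ROIs matrix of cleaned residuals (or a single
#'   series); at least 64 volumes.
#' @param half_lives_tr exponential half-lives in TRs.
#' @param max_lag maximum autocovariance lag used in the fit.
#' @param pooled fit one model on the ROI-averaged autocovariance
#'   (default) or a list of per-ROI models.
#' @param ridge nonnegative jitter added to the lag-0 autocovariance, as a
#'   fraction of its value, to keep the implied Toeplitz covariance
#'   positive definite.
#' @return an object of class `whitening_model` (or a list of them when
#'   `pooled = FALSE`): fields `half_lives_tr`, `weights` (one per
#'   half-life), `residual_variance` (the white component),
#'   `autocov` (model autocovariance at lags `0..max_lag`), `max_lag`.
#' @export
fit_autocorrelation_model <- function(residuals,
                                      half_lives_tr = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                                      max_lag = 128, pooled = TRUE,
                                      ridge = 1e-6) {
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  if (n < 64) stop("need at least 64 volumes to fit the autocovariance model",
                   call. = FALSE)
  if (!all(is.finite(residuals))) {
    stop("residuals contain non-finite values", call. = FALSE)
  }
  p <- min(n - 1L, as.integer(max_lag))
  acov <- function(x) {
    a <- stats::acf(x, lag.max = p, type = "covariance", plot = FALSE,
                    demean = TRUE)
    as.numeric(a$acf)
  }
  fit_one <- function(emp) {
    lags <- 0:p
    B <- vapply(half_lives_tr, function(h) 0.5^(lags / h), numeric(p + 1L))
    B <- cbind(B, as.numeric(lags == 0))  # white component
    w <- pracma::lsqnonneg(B, emp)$x
    k <- length(half_lives_tr)
    model_acov <- as.numeric(B %*% w)
    model_acov[1] <- model_acov[1] * (1 + ridge)
    structure(list(half_lives_tr = half_lives_tr,
                   weights = w[seq_len(k)],
                   residual_variance = w[k + 1L],
                   autocov = model_acov, max_lag = p),
              class = "whitening_model")
  }
  if (pooled) {
    emp <- rowMeans(vapply(seq_len(ncol(residuals)),
                           function(j) acov(residuals[, j]), numeric(p + 1L)))
    fit_one(emp)
  } else {
    lapply(seq_len(ncol(residuals)), function(j) fit_one(acov(residuals[, j])))
  }
}

#' @export
print.whitening_model <- function(x, ...) {
  cat("Eight-exponential autocovariance model\n")
  cat(sprintf("  half-lives (TR): %s\n", paste(x$half_lives_tr, collapse = ", ")))
  cat(sprintf("  weights:         %s\n",
              paste(signif(x$weights, 3), collapse = ", ")))
  cat(sprintf("  white variance:  %.4g; lags fit: 0..%d\n",
              x$residual_variance, x$max_lag))
  invisible(x)
}

# Levinson-Durbin recursion on an autocovariance sequence c[0..p].
# Returns order-m prediction coefficients (rows) and innovation variances,
# i.e. the inverse-Cholesky factor of the stationary Toeplitz covariance
# in banded form.
levinson_durbin <- function(acov) {
  p <- length(acov) - 1L
  a <- matrix(0, p, p)
  v <- numeric(p + 1L)
  v[1] <- acov[1]
  if (p == 0L) return(list(a = a, v = v))
  for (m in 1:p) {
    prev <- if (m > 1) a[m - 1L, 1:(m - 1L)] else numeric(0)
    k <- (acov[m + 1L] - sum(prev * acov[m:2])) / v[m]
    a[m, m] <- k
    if (m > 1) a[m, 1:(m - 1L)] <- prev - k * rev(prev)
    v[m + 1L] <- v[m] * (1 - k^2)
    if (v[m + 1L] <= 0) {
      stop("autocovariance model is not positive definite; increase `ridge`",
           call. = FALSE)
    }
  }
  list(a = a, v = v)
}

#' Prewhiten residual time series
#'
#' Applies the whitening transform implied by a fitted
#' [fit_autocorrelation_model()]: the series is multiplied by the inverse
#' Cholesky factor of the model's (stationary Toeplitz) covariance, computed
#' via the Levinson-Durbin recursion. Each output sample is the normalised
#' one-step prediction error, so white input is returned unchanged up to a
#' global scaling, and autocorrelated input comes out with approximately
#' flat autocorrelation. Length is preserved and the transform is
#' invertible.
#'
#' @param residuals volumes x ROIs matrix (or vector).
#' @param model a `whitening_model`, or a list of one per column.
#' @return whitened matrix with the dimensions and names of `residuals`.
#' @export
whiten <- function(residuals, model) {
  x <- as.matrix(residuals)
  if (inherits(model, "whitening_model")) {
    model <- rep(list(model), ncol(x))
  }
  out <- vapply(seq_len(ncol(x)), function(j) {
    whiten_one(x[, j], model[[j]])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow(x), ncol(x))
  dimnames(out) <- dimnames(residuals)
  if (is.null(dim(residuals))) out <- drop(out)
  out
}

whiten_one <- function(x, model) {
  n <- length(x)
  p <- min(model$max_lag, n - 1L)
  ld <- levinson_durbin(model$autocov[seq_len(p + 1L)])
  y <- numeric(n)
  y[1] <- x[1] / sqrt(ld$v[1])
  if (n == 1L) return(y)
  head_n <- min(p, n - 1L)
  for (t in seq_len(head_n)) {  # growing-order predictors for the first p samples
    pred <- sum(ld$a[t, seq_len(t)] * x[t:1])
    y[t + 1L] <- (x[t + 1L] - pred) / sqrt(ld$v[t + 1L])
  }
  if (n > p + 1L) {  # fixed order-p filter for the stationary part
    E <- stats::embed(x, p + 1L)  # rows: x[t], x[t-1], ..., x[t-p]
    coefs <- c(1, -ld$a[p, seq_len(p)])
    y[(p + 1L):n] <- as.numeric(E %*% coefs) / sqrt(ld$v[p + 1L])
  }
  y
}
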
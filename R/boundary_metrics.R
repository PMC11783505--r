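#' Univariate boundary response of one ROI
#'
#' Quantifies how much an ROI's (cleaned, whitened) signal rises during
#' event-transition periods. The default estimator is the window-mean
#' contrast: mean signal over transition volumes minus mean over
#' within-event volumes. The alternative `"hrf-glm-beta"` regresses the
#' series on the transition indicator convolved with a canonical
#' double-gamma HRF and returns the slope.
#'
#' @param ts_roi numeric series for one ROI.
#' @param bvec a [build_transition_vector()] result (or a plain 0/1 vector
#'   of the same length).
#' @param estimator `"window-mean-contrast"` (default) or `"hrf-glm-beta"`.
#' @return a single number in signal units; exactly 0 for a constant series.
#' @export
boundary_univariate_response <- function(ts_roi, bvec,
                                         estimator = c("window-mean-contrast",
                                                       "hrf-glm-beta")) {
  estimator <- match.arg(estimator)
  ind <- as_indicator(bvec, length(ts_roi))
  if (sum(ind) == 0L || sum(ind) == length(ind)) {
    stop("degenerate boundary vector: both transition and within-event ",
         "volumes are required", call. = FALSE)
  }
  if (estimator == "window-mean-contrast") {
    mean(ts_roi[ind == 1L]) - mean(ts_roi[ind == 0L])
  } else {
    tr_s <- if (inherits(bvec, "boundary_vector")) bvec$tr_s else 2.47
    reg <- hrf_convolve_regressor(as.numeric(ind), tr_s)
    unname(stats::lsfit(reg, ts_roi)$coefficients["X"])
  }
}

#' PPI-style boundary coactivation of an ROI pair
#'
#' Fits a logistic regression predicting the event-boundary transition
#' indicator from two ROI signals and their product:
#' `boundary ~ z1 + z2 + z1:z2`. Both series are z-scored internally before
#' the product is formed, so the statistic is invariant to adding a constant
#' to either input and symmetric in its arguments. The returned value is the
#' interaction (product-term) coefficient — the boundary-locked change in
#' pairwise coupling, controlling for each ROI's own activity, in the manner
#' of a psychophysiological-interaction analysis.
#'
#' If the maximum-likelihood fit shows signs of separation (non-convergence
#' or fitted probabilities pinned at 0/1), the model is refit with a small
#' L2 penalty (`penalty`, default 1.0) on the three slope coefficients and
#' the result is flagged via the `"penalized"` attribute; the reported SE
#' comes from the unpenalised information and should then be read with
#' caution.
#'
#' @param z1,z2 ROI series of equal length.
#' @param bvec transition indicator ([build_transition_vector()] or 0/1
#'   vector); both classes must be non-empty.
#' @param penalty L2 penalty used only for the separation fallback.
#' @return the interaction coefficient, with attributes `se` and
#'   `penalized`.
#' @export
ppi_coactivation <- function(z1, z2, bvec, penalty = 1.0) {
  if (length(z1) != length(z2)) stop("`z1` and `z2` differ in length", call. = FALSE)
  ind <- as_indicator(bvec, length(z1))
  if (sum(ind) == 0L || sum(ind) == length(ind)) {
    stop("degenerate boundary vector: both classes must be non-empty",
         call. = FALSE)
  }
  x1 <- zscore(z1); x2 <- zscore(z2)
  X <- cbind(1, x1, x2, x1 * x2)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, ind, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || max(abs(fit$coefficients)) > 15) sep <- TRUE
  if (sep) {
    co <- ridge_logistic(X, ind, lambda = penalty, penalize = c(FALSE, TRUE, TRUE, TRUE))
    if (is.null(co)) {
      stop("logistic coactivation fit failed to converge even with an L2 penalty",
           call. = FALSE)
    }
    beta <- co
  } else {
    beta <- fit$coefficients
  }
  # SE from the unpenalised Fisher information at the reported coefficients
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  se4 <- tryCatch(sqrt(diag(solve(info)))[4], error = function(e) NA_real_)
  structure(unname(beta[4]), se = unname(se4), penalized = sep)
}

# Newton-Raphson L2-penalised logistic regression; `penalize` marks which
# coefficients carry the penalty. Returns NULL on non-convergence.
ridge_logistic <- function(X, y, lambda, penalize, max_iter = 100, tol = 1e-9) {
  P <- diag(lambda * as.numeric(penalize), ncol(X))
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- crossprod(X, y - mu) - P %*% beta
    H <- crossprod(X * sqrt(pmax(mu * (1 - mu), 1e-10))) + P
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) return(beta)
  }
  NULL
}

#' Boundary coactivation matrix over all ROI pairs
#'
#' Runs [ppi_coactivation()] once per unordered ROI pair and mirrors the
#' interaction coefficients into a symmetric ROI x ROI matrix with an
#' undefined (NA) diagonal.
#'
#' @param ts volumes x ROIs matrix (>= 2 ROIs; column names become ROI
#'   labels).
#' @param bvec transition indicator.
#' @param penalty passed to [ppi_coactivation()].
#' @return symmetric matrix of interaction coefficients, class
#'   `coactivation_matrix`; the `"penalized"` attribute lists pairs that
#'   needed the penalised fallback.
#' @export
coactivation_matrix <- function(ts, bvec, penalty = 1.0) {
  ts <- as.matrix(ts)
  R <- ncol(ts)
  if (R < 2L) stop("need at least 2 ROIs", call. = FALSE)
  labs <- colnames(ts)
  if (is.null(labs)) labs <- sprintf("roi_%02d", seq_len(R))
  M <- matrix(NA_real_, R, R, dimnames = list(labs, labs))
  flagged <- character(0)
  for (i in seq_len(R - 1L)) {
    for (j in (i + 1L):R) {
      b <- tryCatch(
        ppi_coactivation(ts[, i], ts[, j], bvec, penalty = penalty),
        error = function(e) {
          stop(sprintf("pair (%s, %s): %s", labs[i], labs[j],
                       conditionMessage(e)), call. = FALSE)
        })
      if (isTRUE(attr(b, "penalized"))) {
        flagged <- c(flagged, sprintf("%s~%s", labs[i], labs[j]))
      }
      M[i, j] <- M[j, i] <- as.numeric(b)
    }
  }
  structure(M, class = c("coactivation_matrix", "matrix"),
            penalized = flagged)
}

#' Select an all-positive coactive cluster of parcels
#'
#' Given a group-mean coactivation matrix, finds for each candidate
#' super-region the largest subset of its parcels whose pairwise group-mean
#' coactivations are all positive among each other and (optionally) with a
#' designated hippocampus label — the rule used to merge atlas parcels into
#' functional units that jointly increase their coupling at event
#' boundaries. The search enumerates all subsets (candidates are limited to
#' 20 parcels); ties on size are broken by the larger total coactivation.
#' Spatial contiguity is not checked: the inputs carry no geometry, so the
#' all-positive rule alone defines the cluster.
#'
#' @param group_mean symmetric ROI x ROI matrix of group-mean coactivations
#'   with dimnames.
#' @param candidates list of character vectors of parcel labels (a single
#'   vector is accepted).
#' @param hippocampus label of the hippocampal ROI each retained parcel must
#'   also positively coactivate with; `NULL` disables that requirement.
#' @return named list (one element per candidate set) of retained label
#'   vectors; empty vectors, with a warning, where no subset qualifies.
#' @export
select_coactive_cluster <- function(group_mean, candidates, hippocampus = NULL) {
  if (!is.list(candidates)) candidates <- list(candidates)
  if (length(candidates) == 0L) return(list())
  labs <- rownames(group_mean)
  out <- lapply(candidates, function(cand) {
    if (length(cand) == 0L) return(character(0))
    unknown <- setdiff(c(cand, hippocampus), labs)
    if (length(unknown)) {
      stop("unknown parcel label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (length(cand) > 20L) {
      stop("subset enumeration supports at most 20 candidate parcels",
           call. = FALSE)
    }
    best <- character(0); best_sum <- -Inf
    for (mask in seq_len(2^length(cand)) - 1L) {
      sub <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1L)) > 0]
      if (length(sub) == 0L || length(sub) < length(best)) next
      if (all_positive_cluster(group_mean, sub, hippocampus)) {
        s <- cluster_sum(group_mean, sub, hippocampus)
        if (length(sub) > length(best) ||
            (length(sub) == length(best) && s > best_sum)) {
          best <- sub; best_sum <- s
        }
      }
    }
    if (length(best) == 0L) {
      warning("no all-positive subset found for candidate set {",
              paste(cand, collapse = ", "), "}", call. = FALSE)
    }
    best
  })
  names(out) <- names(candidates)
  out
}

# Predicate: all pairwise entries within `sub`, and between `sub` and the
# hippocampus label, are strictly positive. A singleton only qualifies via a
# positive link to the hippocampus; with no hippocampus constraint a cluster
# needs at least two parcels to assert joint coactivation.
all_positive_cluster <- function(M, sub, hippocampus = NULL) {
  if (length(sub) == 0L) return(FALSE)
  if (length(sub) == 1L && is.null(hippocampus)) return(FALSE)
  if (length(sub) >= 2L) {
    block <- M[sub, sub, drop = FALSE]
    off <- block[upper.tri(block)]
    if (any(!is.finite(off)) || any(off <= 0)) return(FALSE)
  }
  if (!is.null(hippocampus)) {
    hc <- M[sub, hippocampus]
    if (any(!is.finite(hc)) || any(hc <= 0)) return(FALSE)
  }
  TRUE
}

cluster_sum <- function(M, sub, hippocampus = NULL) {
  s <- 0
  if (length(sub) >= 2L) {
    block <- M[sub, sub, drop = FALSE]
    s <- s + sum(block[upper.tri(block)])
  }
  if (!is.null(hippocampus)) s <- s + sum(M[sub, hippocampus])
  s
}

#' Merge parcels into super-region time series
#'
#' Averages (unweighted, per volume) the member series of each labelled
#' group — e.g. combining several atlas parcels into one angular-gyrus
#' region, or four hippocampal sub-regions into a single hippocampal ROI.
#'
#' @param ts volumes x ROIs matrix with column names.
#' @param groups named list of character vectors of member labels.
#' @return volumes x groups matrix, columns named after `groups`.
#' @export
merge_rois <- function(ts, groups) {
  ts <- as.matrix(ts)
  unknown <- setdiff(unique(unlist(groups)), colnames(ts))
  if (length(unknown)) {
    stop("unknown ROI label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(groups, function(g) rowMeans(ts[, g, drop = FALSE]),
                numeric(nrow(ts)))
  out <- matrix(out, nrow(ts), length(groups),
                dimnames = list(rownames(ts), names(groups)))
  out
}

#' Write a coactivation matrix as labelled square CSV
#'
#' @param m a [coactivation_matrix()].
#' @param path output file.
#' @param subject_id optional id recorded in an extra leading comment-free
#'   column.
#' @return `path`, invisibly.
#' @export
write_coactivation <- function(m, path, subject_id = NULL) {
  df <- as.data.frame(unclass(m))
  df <- cbind(roi = rownames(m), df)
  if (!is.null(subject_id)) df <- cbind(subject_id = subject_id, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
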
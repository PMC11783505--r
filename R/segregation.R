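#' Global signal regression
#'
#' Removes the mean-over-ROIs time course (plus an intercept) from every ROI
#' series by least squares, the standard adjustment for global vascular
#' fluctuations before whole-scan connectivity. Residuals are orthogonal to
#' the global signal.
#'
#' @param ts volumes x ROIs matrix (>= 1 ROI).
#' @return residual matrix of the same shape.
#' @export
global_signal_regress <- function(ts) {
  ts <- as.matrix(ts)
  gs <- rowMeans(ts)
  res <- qr.resid(qr(cbind(1, gs)), ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Whole-scan ROI correlation matrix
#'
#' Pearson correlation across the full movie duration: unit diagonal,
#' symmetric. Zero-variance ROIs produce NA rows/columns with a warning.
#'
#' @param ts volumes x ROIs matrix with at least 3 volumes.
#' @return ROI x ROI correlation matrix.
#' @export
connectivity_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 volumes", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  flat <- which(sds == 0 | !is.finite(sds))
  C <- suppressWarnings(stats::cor(ts))
  if (length(flat)) {
    warning(sprintf("zero-variance ROI(s): %s; correlations set to NA",
                    paste(colnames(ts)[flat], collapse = ", ")), call. = FALSE)
    C[flat, ] <- NA_real_
    C[, flat] <- NA_real_
  }
  diag(C) <- 1
  C
}

#' Brain-network system segregation
#'
#' Computes the system segregation (SyS) statistic of a connectivity matrix
#' under a partition of ROIs into networks: the difference between mean
#' within-network and mean between-network connectivity, scaled by the
#' within-network mean,
#'
#' `SyS = (mean_within - mean_between) / mean_within`.
#'
#' Means are taken over off-diagonal ROI pairs (each unordered pair once).
#' By default raw Pearson correlations are averaged with negative values
#' retained; `fisher_z` averages Fisher-z transforms (back-transformed for
#' reporting), and `drop_negative` zeroes negative correlations first. When
#' the within-network mean is not positive the statistic is undefined and
#' returned as NA with `defined = FALSE`.
#'
#' @param conn ROI x ROI correlation matrix, e.g. [connectivity_matrix()].
#' @param partition named vector mapping ROI label -> network label (or a
#'   two-column data frame `roi_label`, `network_label`). At least two
#'   networks, each contributing within-pairs.
#' @param fisher_z average Fisher-z transformed correlations.
#' @param drop_negative zero out negative correlations before averaging.
#' @param partition_id label stored in the result.
#' @return object of class `segregation_result`: `mean_within`,
#'   `mean_between`, `sys`, `defined`, `partition_id`.
#' @export
system_segregation <- function(conn, partition, fisher_z = FALSE,
                               drop_negative = FALSE, partition_id = "default") {
  if (is.data.frame(partition)) {
    partition <- stats::setNames(as.character(partition[[2]]),
                                 as.character(partition[[1]]))
  }
  labs <- rownames(conn)
  if (is.null(labs)) labs <- names(partition)
  missing_labs <- setdiff(labs, names(partition))
  if (length(missing_labs)) {
    stop("partition is missing ROI(s): ", paste(missing_labs, collapse = ", "),
         call. = FALSE)
  }
  net <- partition[labs]
  if (length(unique(net)) < 2L) {
    stop("need at least two networks", call. = FALSE)
  }
  if (any(table(net) < 2L)) {
    stop("every network needs >= 2 ROIs to contribute within-network pairs",
         call. = FALSE)
  }
  R <- nrow(conn)
  same <- outer(net, net, "==")
  ut <- upper.tri(conn)
  vals <- conn[ut]
  if (drop_negative) vals <- pmax(vals, 0)
  if (fisher_z) vals <- atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12))
  within_vals <- vals[same[ut]]
  between_vals <- vals[!same[ut]]
  if (length(within_vals) == 0L) {
    stop("no within-network pairs: every network needs >= 2 ROIs", call. = FALSE)
  }
  mw <- mean(within_vals); mb <- mean(between_vals)
  if (fisher_z) { mw <- tanh(mw); mb <- tanh(mb) }
  defined <- is.finite(mw) && mw > 0
  sys <- if (defined) (mw - mb) / mw else NA_real_
  if (!defined) {
    warning("mean within-network connectivity is not positive; SyS undefined",
            call. = FALSE)
  }
  structure(list(mean_within = mw, mean_between = mb, sys = sys,
                 defined = defined, partition_id = partition_id),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "System segregation (%s): within %.3f, between %.3f, SyS = %s\n",
    x$partition_id, x$mean_within, x$mean_between,
    if (x$defined) sprintf("%.3f", x$sys) else "undefined"))
  invisible(x)
}

#' Read a network partition from CSV
#'
#' @param path two-column CSV (`roi_label`, `network_label`).
#' @return named character vector ROI -> network.
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("partition CSV needs two columns", call. = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
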
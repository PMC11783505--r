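#' Group APOE genotypes for analysis
#'
#' Collapses genotypes into the two-level analysis factor: `e3/e4` and
#' `e4/e4` become the `e4+` group, `e3/e3` is the reference, and epsilon-2
#' carriers are excluded (their count is reported in a message).
#'
#' @param cohort data frame with a `genotype` column over
#'   `c("e3/e3","e3/e4","e4/e4","e2-carrier")`.
#' @return the retained rows with an added `group` factor
#'   (levels `c("e3/e3","e4+")`).
#' @export
group_genotypes <- function(cohort) {
  g <- cohort$genotype
  if (is.null(g)) stop("`cohort` has no genotype column", call. = FALSE)
  unknown <- setdiff(unique(g), GENOTYPE_LEVELS)
  if (length(unknown)) {
    stop("unknown genotype value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n_e2 <- sum(g == "e2-carrier")
  if (n_e2 > 0) {
    message(sprintf("excluding %d epsilon-2 carrier(s)", n_e2))
  }
  out <- cohort[g != "e2-carrier", , drop = FALSE]
  out$group <- factor(ifelse(out$genotype == "e3/e3", "e3/e3", "e4+"),
                      levels = c("e3/e3", "e4+"))
  out
}

#' Flag outliers by the 1.5 x IQR rule on age-adjusted residuals
#'
#' Regresses `y` on a quadratic polynomial of age (collinear columns, e.g.
#' under constant age, are pivoted out) and flags observations whose
#' residual lies below `Q1 - 1.5*IQR` or above `Q3 + 1.5*IQR` of the
#' residual distribution. With zero residual IQR the fences collapse to a
#' point and only residuals strictly outside it are flagged, so identical
#' `y` values are never flagged.
#'
#' @param y dependent variable.
#' @param age ages in years (same length; n >= 5).
#' @return logical vector, `TRUE` marking outliers.
#' @export
flag_outliers_iqr <- function(y, age) {
  if (length(y) != length(age)) stop("`y` and `age` differ in length", call. = FALSE)
  if (length(y) < 5L) stop("need at least 5 observations", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(age))) {
    stop("`y` and `age` must be finite", call. = FALSE)
  }
  X <- cbind(1, age, age^2)
  r <- qr.resid(qr(X), y)
  q <- stats::quantile(r, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  # guard against flagging pure floating-point jitter around an exact fit
  tol <- sqrt(.Machine$double.eps) * max(1, abs(y))
  r < q[1] - 1.5 * iqr - tol | r > q[2] + 1.5 * iqr + tol
}

#' Fit the genotype-by-age phenotype model
#'
#' The central phenotype model: for one dependent variable `y` (a boundary
#' univariate response, a pairwise coactivation, or a segregation score, one
#' value per subject), fit the ordinary-least-squares model
#'
#' `y ~ 1 + z(age) + z(z(age)^2) + group + group:z(age) + group:z(z(age)^2)`
#'
#' where `z()` is z-scoring on the analysed sample, the quadratic term is
#' the square of z-scored age, itself re-z-scored, and `group` codes `e4+`
#' as 1 against the `e3/e3` reference. Each term is reported with its
#' estimate, SE, two-tailed t-test, and a Bayes factor `BF01` quantifying
#' evidence for that term's absence ([bayes_factor_null()]); p-values are
#' left uncorrected. Outliers on `y` are, by default, removed first by the
#' age-adjusted 1.5 x IQR rule ([flag_outliers_iqr()]). Per-group quadratic
#' age fits are retained for plotting.
#'
#' @param y dependent variable, one value per subject.
#' @param age ages in years.
#' @param group factor with reference level first (e.g. from
#'   [group_genotypes()]), or a 0/1 vector.
#' @param remove_outliers apply [flag_outliers_iqr()] before fitting
#'   (default `TRUE`).
#' @param bf_method,bf_r,bf_terms Bayes-factor options: method and Cauchy
#'   prior scale passed to [bayes_factor_null()], and which terms get a BF
#'   (default: the three genotype terms).
#' @param dv_name label stored in the result.
#' @return an object of class `apoe_fit` with components `terms` (data
#'   frame: estimate, se, t, p, bf01 per term), `adj_r2`, `df`, `n`,
#'   `outlier_mask`, `group_fits`, `data`. Methods: `print`, `summary`,
#'   `coef`, `residuals`, `plot`.
#' @export
fit_genotype_age_model <- function(y, age, group, remove_outliers = TRUE,
                                   bf_method = c("jzs", "mc"),
                                   bf_r = sqrt(2) / 2,
                                   bf_terms = c("apoe", "apoe_x_age", "apoe_x_age2"),
                                   dv_name = deparse(substitute(y))) {
  bf_method <- match.arg(bf_method)
  if (is.factor(group)) group <- as.numeric(group) - 1
  group <- as.numeric(group)
  if (!all(group %in% c(0, 1))) stop("`group` must be two-level", call. = FALSE)
  keep_complete <- is.finite(y) & is.finite(age) & is.finite(group)
  y <- y[keep_complete]; age <- age[keep_complete]; group <- group[keep_complete]
  if (length(unique(group)) < 2L) {
    stop("both genotype groups must be represented", call. = FALSE)
  }

  out_mask <- if (remove_outliers) flag_outliers_iqr(y, age) else rep(FALSE, length(y))
  yk <- y[!out_mask]; agek <- age[!out_mask]; gk <- group[!out_mask]
  za <- zscore(agek)
  zq <- zscore(za^2)
  X <- cbind(intercept = 1, age_linear = za, age_quadratic = zq,
             apoe = gk, apoe_x_age = gk * za, apoe_x_age2 = gk * zq)
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2L) stop("too few observations after outlier removal", call. = FALSE)

  qrX <- qr(X)
  if (qrX$rank < k) stop("rank-deficient phenotype design", call. = FALSE)
  beta <- qr.coef(qrX, yk)
  res <- qr.resid(qrX, yk)
  df <- n - k
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((yk - mean(yk))^2)
  adj_r2 <- if (tss > 0) 1 - (sum(res^2) / df) / (tss / (n - 1)) else NA_real_

  bf01 <- rep(NA_real_, k)
  names(bf01) <- colnames(X)
  for (term in intersect(bf_terms, colnames(X))) {
    j <- match(term, colnames(X))
    bf01[j] <- bayes_factor_null(yk, X, term = j, method = bf_method, r = bf_r)
  }

  terms <- data.frame(term = colnames(X), estimate = unname(beta),
                      se = unname(se), t = unname(tval), p = unname(pval),
                      bf01 = unname(bf01), row.names = NULL)
  group_fits <- lapply(split(seq_len(n), gk), function(idx) {
    stats::lm.fit(cbind(1, za[idx], za[idx]^2), yk[idx])$coefficients
  })

  structure(list(dv_name = dv_name, terms = terms, adj_r2 = adj_r2, df = df,
                 n = n, outlier_mask = out_mask,
                 group_fits = group_fits, bf_method = bf_method, bf_r = bf_r,
                 data = data.frame(y = yk, age = agek, group = gk),
                 fitted = yk - res, residuals = res),
            class = "apoe_fit")
}

#' @export
print.apoe_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Genotype-by-age model for '%s'\n", x$dv_name))
  cat(sprintf("  n = %d (outliers removed: %d), adj R^2 = %.3f, df = %d\n",
              x$n, sum(x$outlier_mask), x$adj_r2, x$df))
  tab <- x$terms
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$t <- signif(tab$t, digits)
  tab$p <- signif(tab$p, digits)
  tab$bf01 <- signif(tab$bf01, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.apoe_fit <- function(object, ...) {
  object
}

#' @export
coef.apoe_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

#' @export
residuals.apoe_fit <- function(object, ...) object$residuals

#' Plot a fitted genotype-by-age model
#'
#' Scatter of the dependent variable against age, coloured by genotype
#' group, with each group's quadratic age fit overlaid — the standard way
#' these phenotype models are inspected.
#'
#' @param x an `apoe_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.apoe_fit <- function(x, ...) {
  d <- x$data
  cols <- c("#3366AA", "#EE6677")
  graphics::plot(d$age, d$y, col = cols[d$group + 1], pch = 16, cex = 0.6,
                 xlab = "age (years)", ylab = x$dv_name, ...)
  za_all <- zscore(d$age)
  ord <- order(d$age)
  for (g in 0:1) {
    cf <- x$group_fits[[as.character(g)]]
    if (is.null(cf) || anyNA(cf)) next
    yy <- cf[1] + cf[2] * za_all + cf[3] * za_all^2
    graphics::lines(d$age[ord], yy[ord], col = cols[g + 1], lwd = 2)
  }
  graphics::legend("topright", legend = c("e3/e3", "e4+"), col = cols,
                   pch = 16, bty = "n")
  invisible(x)
}

#' Genotype-model report table for a set of dependent variables
#'
#' Fits [fit_genotype_age_model()] to every column of `dvs` and stacks the
#' per-term results into one long table shaped like the phenotype report:
#' one row per dependent variable x term with estimate, SE, t, p, BF01,
#' adjusted R-squared and residual df.
#'
#' @param dvs data frame or matrix of dependent variables (one column per
#'   DV, one row per subject).
#' @param age,group as in [fit_genotype_age_model()].
#' @param skip_degenerate drop (with a warning) dependent variables whose
#'   model cannot be fit — e.g. all-missing columns — instead of stopping.
#' @param ... passed to [fit_genotype_age_model()].
#' @return data frame with columns `dependent_variable`, `term`,
#'   `estimate`, `se`, `t`, `p`, `bf01`, `adj_r2`, `df`, `n_outliers`; the
#'   `"skipped"` attribute names any dropped variables.
#' @export
genotype_report <- function(dvs, age, group, skip_degenerate = FALSE, ...) {
  dvs <- as.data.frame(dvs)
  skipped <- character(0)
  rows <- lapply(names(dvs), function(nm) {
    fit <- tryCatch(
      fit_genotype_age_model(dvs[[nm]], age, group, dv_name = nm, ...),
      error = function(e) {
        if (!skip_degenerate) stop(e)
        warning(sprintf("skipping dependent variable '%s': %s", nm,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(fit)) {
      skipped <<- c(skipped, nm)
      return(NULL)
    }
    cbind(dependent_variable = nm, fit$terms,
          adj_r2 = fit$adj_r2, df = fit$df,
          n_outliers = sum(fit$outlier_mask))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_report_table()
  attr(out, "skipped") <- skipped
  out
}
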
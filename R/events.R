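#' Consensus event boundaries from observer annotations
#'
#' Observers watching a continuous movie press a key whenever they feel one
#' meaningful event has ended and another begun. Individual clicks are noisy,
#' so boundaries are defined by consensus: nearby clicks are grouped into
#' candidate boundaries by single-linkage clustering (two clicks belong to
#' the same candidate if they are within `merge_tolerance_s` of each other,
#' directly or through a chain), and a candidate is kept only if at least
#' `ceiling(threshold * n_observers)` distinct observers contributed to it.
#' With 16 observers and the default 50% threshold, a candidate marked by 8
#' observers is kept while one marked by 7 is dropped.
#'
#' @param annotations data frame with columns `observer_id` and `onset_s`
#'   (seconds from movie start), e.g. from [generate_observer_annotations()]
#'   or [read_annotations()].
#' @param n_observers total number of observers in the experiment. Defaults
#'   to the `n_observers` attribute of `annotations` if present, otherwise to
#'   the number of distinct observer ids. Observers who never clicked still
#'   count toward the denominator, so pass this explicitly when they exist.
#' @param threshold minimum proportion of observers required, in (0, 1].
#' @param merge_tolerance_s single-linkage merge tolerance in seconds;
#'   defaults to one TR of the emulated design (2.47 s).
#' @return numeric vector of consensus onsets in seconds (cluster means),
#'   sorted increasing. Empty annotations give an empty vector.
#' @seealso [build_transition_vector()]
#' @examples
#' ann <- data.frame(observer_id = rep(1:8, each = 1), onset_s = rnorm(8, 30, 0.3))
#' consensus_boundaries(ann, n_observers = 16)
#' @export
consensus_boundaries <- function(annotations, n_observers = NULL,
                                 threshold = 0.5, merge_tolerance_s = 2.47) {
  stopifnot_scalar(threshold, "threshold", lower = 1e-12, upper = 1)
  stopifnot_scalar(merge_tolerance_s, "merge_tolerance_s", lower = 0)
  if (!all(c("observer_id", "onset_s") %in% names(annotations))) {
    stop("`annotations` needs columns observer_id and onset_s", call. = FALSE)
  }
  if (is.null(n_observers)) {
    n_observers <- attr(annotations, "n_observers")
    if (is.null(n_observers)) n_observers <- length(unique(annotations$observer_id))
  }
  if (nrow(annotations) == 0L) return(numeric(0))
  if (any(annotations$onset_s < 0)) stop("annotation onsets must be >= 0", call. = FALSE)

  ord <- order(annotations$onset_s)
  t <- annotations$onset_s[ord]
  obs <- annotations$observer_id[ord]
  # single-linkage chains on a sorted line: cut where consecutive gap exceeds tol
  new_cluster <- c(TRUE, diff(t) > merge_tolerance_s)
  cl <- cumsum(new_cluster)
  need <- ceiling(threshold * n_observers)
  keep <- vapply(split(obs, cl), function(o) length(unique(o)) >= need, logical(1))
  onsets <- vapply(split(t, cl), mean, numeric(1))[keep]
  sort(unname(onsets))
}

#' Event-transition window for a boundary onset
#'
#' For a boundary at `onset_s` seconds, the transition period spans
#' `window_tr` repetition times on each side of the onset, then is shifted
#' forward by `lag_tr` TRs to account for the hemodynamic lag. With TR =
#' 2.47 s and a ±2 TR window, an onset 30 s into the movie gives the
#' pre-shift window [25.06, 34.94] s; the default 2-TR lag moves it to
#' [30.00, 39.88] s.
#'
#' @param onset_s boundary onset in seconds.
#' @param tr_s repetition time in seconds.
#' @param window_tr window half-width in TRs (default 2).
#' @param lag_tr hemodynamic shift in TRs; use 0 for the pre-shift window.
#' @return numeric vector `c(start, end)` in seconds.
#' @export
transition_window <- function(onset_s, tr_s = 2.47, window_tr = 2, lag_tr = 0) {
  stopifnot_scalar(tr_s, "tr_s", lower = 1e-12)
  stopifnot_scalar(onset_s, "onset_s")
  c(start = onset_s - window_tr * tr_s + lag_tr * tr_s,
    end   = onset_s + window_tr * tr_s + lag_tr * tr_s)
}

#' Per-volume boundary transition indicator
#'
#' Converts consensus boundary onsets into a binary vector over scan volumes:
#' 1 for volumes inside any (lag-shifted) transition window, 0 for
#' within-event volumes. Volume `i` (0-based) is attributed the onset time
#' `i * tr_s` and is marked when that time falls in the half-open applied
#' window `[start, end)`. Overlapping windows are unioned; windows are
#' clipped at the scan edges.
#'
#' @param boundaries numeric vector of boundary onsets in seconds, e.g. from
#'   [consensus_boundaries()]. Onsets outside `[0, n_vols * tr_s)` are an
#'   error naming the offending onset.
#' @param tr_s repetition time in seconds.
#' @param n_vols number of volumes in the scan.
#' @param window_tr window half-width in TRs (default 2).
#' @param lag_tr hemodynamic shift in TRs (default 2, roughly 5 s at
#'   TR = 2.47 s).
#' @return an object of class `boundary_vector`: a list with `indicator`
#'   (integer 0/1 of length `n_vols`), `tr_s`, `window_tr`, `lag_tr`, and
#'   `onsets_s`.
#' @export
build_transition_vector <- function(boundaries, tr_s, n_vols,
                                    window_tr = 2, lag_tr = 2) {
  stopifnot_scalar(tr_s, "tr_s", lower = 1e-12)
  stopifnot_scalar(n_vols, "n_vols", lower = 1)
  n_vols <- as.integer(n_vols)
  dur <- n_vols * tr_s
  bad <- boundaries[boundaries < 0 | boundaries >= dur]
  if (length(bad)) {
    stop(sprintf("boundary onset(s) outside the scan [0, %.2f): %s",
                 dur, paste(format(bad), collapse = ", ")), call. = FALSE)
  }
  ind <- integer(n_vols)
  times <- (seq_len(n_vols) - 1L) * tr_s
  for (b in boundaries) {
    w <- transition_window(b, tr_s, window_tr = window_tr, lag_tr = lag_tr)
    ind[times >= w[1] & times < w[2]] <- 1L
  }
  structure(list(indicator = ind, tr_s = tr_s, window_tr = window_tr,
                 lag_tr = lag_tr, onsets_s = sort(boundaries)),
            class = "boundary_vector")
}

#' @export
print.boundary_vector <- function(x, ...) {
  cat(sprintf(
    "Boundary transition vector: %d volumes (TR %.3f s), %d boundaries,\n  window +/-%d TR shifted %d TR; %d transition volumes (%.1f%%)\n",
    length(x$indicator), x$tr_s, length(x$onsets_s), x$window_tr, x$lag_tr,
    sum(x$indicator), 100 * mean(x$indicator)))
  invisible(x)
}

# Coerce either a boundary_vector or a plain 0/1 vector to the indicator.
as_indicator <- function(bvec, n = NULL) {
  ind <- if (inherits(bvec, "boundary_vector")) bvec$indicator else bvec
  if (!all(ind %in% c(0, 1))) stop("indicator must be binary", call. = FALSE)
  if (!is.null(n) && length(ind) != n) {
    stop(sprintf("indicator length %d does not match series length %d",
                 length(ind), n), call. = FALSE)
  }
  as.integer(ind)
}

#' Read observer annotations from CSV
#'
#' @param path CSV file with columns `observer_id`, `onset_s`.
#' @param n_observers total observer count (see [consensus_boundaries()]).
#' @return annotation data frame with an `n_observers` attribute.
#' @export
read_annotations <- function(path, n_observers = NULL) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("observer_id", "onset_s") %in% names(ann))) {
    stop("annotation CSV needs columns observer_id, onset_s", call. = FALSE)
  }
  attr(ann, "n_observers") <-
    if (is.null(n_observers)) length(unique(ann$observer_id)) else n_observers
  ann
}

#' Write boundary onsets or a transition vector to CSV
#'
#' `write_boundaries()` writes a one-column CSV of onsets in seconds;
#' `write_boundary_vector()` writes `volume` (0-based) and `transition`
#' columns.
#'
#' @param boundaries numeric vector of onsets in seconds.
#' @param bvec a `boundary_vector`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  utils::write.csv(data.frame(onset_s = boundaries), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
write_boundary_vector <- function(bvec, path) {
  utils::write.csv(data.frame(volume = seq_along(bvec$indicator) - 1L,
                              transition = bvec$indicator),
                   path, row.names = FALSE)
  invisible(path)
}
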
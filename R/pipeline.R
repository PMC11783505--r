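#' Pipeline run configuration
#'
#' Collects every stage toggle and parameter of [run_pipeline()] in one
#' validated object. The configuration round-trips through YAML
#' ([write_run_config()] / [read_run_config()]) unchanged, and every random
#' stage draws its seed deterministically from `seed`, so a configuration
#' fully determines a run.
#'
#' @param stages character vector of stages to execute, a subset of
#'   `c("simulate", "preprocess", "boundaries", "metrics", "segregate",
#'   "genostats", "classify")` (executed in that order). An empty vector is
#'   a no-op run.
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param window_tr,lag_tr transition-window geometry (TRs).
#' @param cutoff_hz high-pass cutoff for the DCT set.
#' @param half_lives_tr autocovariance model half-life grid (TRs).
#' @param consensus_threshold,merge_tolerance_s consensus-boundary
#'   parameters.
#' @param n_observers,miss_rate,jitter_sd simulated annotation-experiment
#'   parameters.
#' @param metric_rois ROI labels used for the pairwise coactivation
#'   dependent variables in the genotype models (`NULL` = all ROIs; the
#'   classifier always uses the full matrix).
#' @param k_folds,n_perm,svm_cost classification settings.
#' @param bf_method,bf_r Bayes-factor settings (see [bayes_factor_null()]).
#' @param partition named ROI -> network vector for the segregation stage;
#'   `NULL` splits the ROIs into two equal networks.
#' @param out_dir where [run_pipeline()] writes its report; `NULL` skips
#'   writing.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "preprocess", "boundaries",
                                  "metrics", "segregate", "genostats",
                                  "classify"),
                       sim = sim_config(),
                       window_tr = 2, lag_tr = 2,
                       cutoff_hz = 0.008,
                       half_lives_tr = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                       consensus_threshold = 0.5,
                       merge_tolerance_s = sim$tr_s,
                       n_observers = 16, miss_rate = 0.1, jitter_sd = 1,
                       metric_rois = NULL,
                       k_folds = 5, n_perm = 5000, svm_cost = 1,
                       bf_method = "jzs", bf_r = sqrt(2) / 2,
                       partition = NULL,
                       out_dir = NULL,
                       seed = 1L) {
  known <- c("simulate", "preprocess", "boundaries", "metrics", "segregate",
             "genostats", "classify")
  if (length(setdiff(stages, known))) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }
  structure(list(stages = intersect(known, stages), sim = sim,
                 window_tr = window_tr, lag_tr = lag_tr,
                 cutoff_hz = cutoff_hz, half_lives_tr = half_lives_tr,
                 consensus_threshold = consensus_threshold,
                 merge_tolerance_s = merge_tolerance_s,
                 n_observers = n_observers, miss_rate = miss_rate,
                 jitter_sd = jitter_sd, metric_rois = metric_rois,
                 k_folds = k_folds, n_perm = n_perm, svm_cost = svm_cost,
                 bf_method = bf_method, bf_r = bf_r, partition = partition,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialise / restore a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass_deep(config), precision = 15), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$sim
  sim$genotype_freqs <- unlist(sim$genotype_freqs)
  raw$sim <- do.call(sim_config, sim)
  if (!is.null(raw$partition)) raw$partition <- unlist(raw$partition)
  do.call(run_config, raw)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    x <- as.list(x)  # keep names: yaml maps named vectors only via lists
  }
  x
}

# Fingerprint of a configuration, recorded in run logs.
config_hash <- function(config) {
  fnv1a32(yaml::as.yaml(unclass_deep(config)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, preprocess (nuisance
#' regression + DCT filtering + prewhitening), boundaries (annotation
#' consensus + transition vector), metrics (univariate boundary responses
#' and pairwise coactivation), segregate (global signal regression +
#' connectivity + SyS), genostats (genotype-by-age models with Bayes
#' factors over every dependent variable), classify (permutation-tested
#' linear-SVM genotype classification) — and returns a report bundle. A
#' stage failure halts the run naming the stage. If `config$out_dir` is
#' set the bundle is also written via [write_report()].
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_report`: list with `genostats` (long
#'   term table), `classification` (a `permutation_result` or `NULL`),
#'   `segregation` (per-subject data frame or `NULL`), `boundaries`,
#'   `config`, `log` (character vector).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("run started; config hash %s", config_hash(config)),
           sprintf("stages: %s", paste(config$stages, collapse = ", ")))
  note <- function(...) log <<- c(log, sprintf(...))
  on_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  has <- function(s) s %in% config$stages

  dataset <- NULL; cleaned <- NULL; bvec <- NULL
  dvs <- NULL; grouped <- NULL
  genostats_tab <- empty_report_table()
  classification <- NULL; segregation <- NULL; boundaries <- NULL

  if (has("simulate")) {
    dataset <- on_stage("simulate", generate_dataset(config$sim))
    note("simulated %d subjects (%d ROIs x %d volumes)",
         nrow(dataset$cohort), config$sim$n_rois, config$sim$n_vols)
  }

  if (has("preprocess")) {
    if (is.null(dataset)) stop("pipeline stage 'preprocess' failed: no input data (enable 'simulate' or supply data)", call. = FALSE)
    cleaned <- on_stage("preprocess", {
      dct <- dct_basis(config$sim$n_vols, config$sim$tr_s, config$cutoff_hz)
      lapply(dataset$subjects, function(s) {
        conf <- build_confound_matrix(s$confounds[, 1:6], s$confounds[, "wm"],
                                      s$confounds[, "csf"])
        res <- clean_timeseries(s$ts, conf, dct)
        model <- fit_autocorrelation_model(res, half_lives_tr = config$half_lives_tr)
        whiten(res, model)
      })
    })
    note("preprocessed %d subjects (32 confounds + %d DCT columns)",
         length(cleaned),
         ncol(dct_basis(config$sim$n_vols, config$sim$tr_s, config$cutoff_hz)))
  } else if (!is.null(dataset)) {
    cleaned <- lapply(dataset$subjects, function(s) s$ts)
  }

  if (has("boundaries")) {
    boundaries <- on_stage("boundaries", {
      ann <- generate_observer_annotations(
        config$sim$boundary_onsets_s, n_observers = config$n_observers,
        miss_rate = config$miss_rate, jitter_sd = config$jitter_sd,
        duration_s = config$sim$n_vols * config$sim$tr_s,
        seed = config$seed + 17L)
      consensus_boundaries(ann, n_observers = config$n_observers,
                           threshold = config$consensus_threshold,
                           merge_tolerance_s = config$merge_tolerance_s)
    })
    bvec <- build_transition_vector(boundaries, config$sim$tr_s,
                                    config$sim$n_vols,
                                    window_tr = config$window_tr,
                                    lag_tr = config$lag_tr)
    note("consensus boundaries: %d; transition volumes: %d",
         length(boundaries), sum(bvec$indicator))
  }

  coact <- NULL
  if (has("metrics")) {
    if (is.null(cleaned) || is.null(bvec)) {
      stop("pipeline stage 'metrics' failed: needs preprocessed data and boundaries", call. = FALSE)
    }
    on_stage("metrics", {
      roi_labs <- colnames(cleaned[[1]])
      metric_rois <- if (is.null(config$metric_rois)) roi_labs else config$metric_rois
      uni <- t(vapply(cleaned, function(ts) {
        vapply(seq_len(ncol(ts)),
               function(j) boundary_univariate_response(ts[, j], bvec),
               numeric(1))
      }, numeric(length(roi_labs))))
      colnames(uni) <- paste0("uni_", roi_labs)
      coact <- lapply(cleaned, coactivation_matrix, bvec = bvec)
      pair_feats <- vectorize_coactivation(coact)
      keep <- outer(metric_rois, metric_rois,
                    function(a, b) paste0(a, "~", b))
      pair_sub <- pair_feats[, colnames(pair_feats) %in% keep, drop = FALSE]
      colnames(pair_sub) <- paste0("coact_", colnames(pair_sub))
      dvs <- cbind(as.data.frame(uni), as.data.frame(pair_sub))
      note("metrics: %d univariate + %d coactivation dependent variables",
           ncol(uni), ncol(pair_sub))
    })
  }

  if (has("segregate")) {
    if (is.null(cleaned)) stop("pipeline stage 'segregate' failed: no time series", call. = FALSE)
    segregation <- on_stage("segregate", {
      labs <- colnames(cleaned[[1]])
      part <- config$partition
      if (is.null(part)) {
        # default to the generator's modular structure: first half net_A
        half <- ceiling(length(labs) / 2)
        part <- stats::setNames(rep(c("net_A", "net_B"),
                                    c(half, length(labs) - half)), labs)
      }
      n_undef <- 0L
      rows <- withCallingHandlers(
        lapply(names(cleaned), function(id) {
          sr <- system_segregation(connectivity_matrix(
            global_signal_regress(cleaned[[id]])), part)
          data.frame(subject_id = id, mean_within = sr$mean_within,
                     mean_between = sr$mean_between, sys = sr$sys)
        }),
        warning = function(w) {
          if (grepl("SyS undefined", conditionMessage(w))) {
            n_undef <<- n_undef + 1L
            invokeRestart("muffleWarning")
          }
        })
      if (n_undef > 0L) note("SyS undefined for %d subject(s)", n_undef)
      do.call(rbind, rows)
    })
    if (!is.null(dvs)) dvs$sys <- segregation$sys
    else dvs <- data.frame(sys = segregation$sys)
    note("segregation computed for %d subjects", nrow(segregation))
  }

  if (has("genostats")) {
    if (is.null(dataset) || is.null(dvs)) {
      stop("pipeline stage 'genostats' failed: needs a cohort and dependent variables", call. = FALSE)
    }
    genostats_tab <- on_stage("genostats", {
      grouped <- group_genotypes(dataset$cohort)
      keep <- match(grouped$subject_id, dataset$cohort$subject_id)
      suppressWarnings(
        genotype_report(dvs[keep, , drop = FALSE], grouped$age, grouped$group,
                        skip_degenerate = TRUE,
                        bf_method = config$bf_method, bf_r = config$bf_r))
    })
    note("genotype models: %d dependent variables (%d subjects: %d e4+, %d e3/e3)",
         length(unique(genostats_tab$dependent_variable)), nrow(grouped),
         sum(grouped$group == "e4+"), sum(grouped$group == "e3/e3"))
    if (length(attr(genostats_tab, "skipped"))) {
      note("skipped degenerate dependent variable(s): %s",
           paste(attr(genostats_tab, "skipped"), collapse = ", "))
    }
  }

  if (has("classify")) {
    if (is.null(coact) || is.null(dataset)) {
      stop("pipeline stage 'classify' failed: needs coactivation matrices", call. = FALSE)
    }
    classification <- on_stage("classify", {
      if (is.null(grouped)) grouped <- suppressMessages(group_genotypes(dataset$cohort))
      keep <- match(grouped$subject_id, names(coact))
      feats <- vectorize_coactivation(coact[keep])
      permutation_test(feats, grouped$group, n_perm = config$n_perm,
                       k = config$k_folds, seed = config$seed + 29L,
                       cost = config$svm_cost)
    })
    note("classification: bAcc %.3f, p = %.4g",
         classification$observed_bacc, classification$p)
  }

  report <- structure(list(genostats = genostats_tab,
                           classification = classification,
                           segregation = segregation,
                           boundaries = boundaries,
                           config = config, log = log),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

empty_report_table <- function() {
  data.frame(dependent_variable = character(0), term = character(0),
             estimate = numeric(0), se = numeric(0), t = numeric(0),
             p = numeric(0), bf01 = numeric(0), adj_r2 = numeric(0),
             df = numeric(0), n_outliers = numeric(0))
}

#' Write a pipeline report bundle
#'
#' Writes the genotype-model table as `genostats.csv` (one row per
#' dependent variable x term; columns `dependent_variable`, `term`,
#' `estimate`, `se`, `t`, `p`, `bf01`, `adj_r2`, `df`, `n_outliers`;
#' numbers are printed with full precision so the table round-trips through
#' [read_report_table()] exactly), the classification result as
#' `classification.json`, per-subject segregation as `segregation.csv`, the
#' configuration as `config.yaml`, and the run log (stamped with the config
#' hash) as `run_log.txt`, plus a short `summary.txt`. An empty result
#' writes a header-only table.
#'
#' @param report a `pipeline_report` (or a bare genostats table).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (is.data.frame(report)) {
    report <- structure(list(genostats = report, classification = NULL,
                             segregation = NULL, boundaries = NULL,
                             config = NULL, log = character(0)),
                        class = "pipeline_report")
  }
  tab <- report$genostats
  need <- names(empty_report_table())
  if (!all(need %in% names(tab))) {
    stop("genostats table is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_numeric_csv(tab[need], file.path(dir, "genostats.csv"))
  if (!is.null(report$segregation)) {
    write_numeric_csv(report$segregation, file.path(dir, "segregation.csv"))
  }
  if (!is.null(report$classification)) {
    cl <- report$classification
    jsonlite::write_json(list(observed_bacc = cl$observed_bacc, p = cl$p,
                              n_perm = cl$n_perm, k_folds = cl$k_folds,
                              seed = cl$seed),
                         file.path(dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$config)) {
    write_run_config(report$config, file.path(dir, "config.yaml"))
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  writeLines(c(sprintf("dependent variables: %d",
                       length(unique(tab$dependent_variable))),
               sprintf("rows: %d", nrow(tab)),
               if (!is.null(report$classification))
                 sprintf("classification bAcc %.3f (p = %.4g)",
                         report$classification$observed_bacc,
                         report$classification$p)),
             file.path(dir, "summary.txt"))
  invisible(dir)
}

# CSV writer that prints doubles with 17 significant digits so that
# read-back reproduces them bit-exactly.
write_numeric_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a report table written by [write_report()]
#'
#' @param path path to `genostats.csv` (or any [write_numeric_csv()]-style
#'   table).
#' @return data frame with numeric columns restored.
#' @export
read_report_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (all(grepl("^[-+0-9eE.naif]*$", df[[j]])) &&
        any(grepl("[0-9]", df[[j]]))) {
      suppressWarnings(num <- as.numeric(df[[j]]))
      if (!anyNA(num) || all(is.na(num) == (df[[j]] %in% c("NA", "nan", "inf")))) {
        df[[j]] <- num
      }
    }
  }
  df
}
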
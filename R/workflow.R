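#' Pipeline configuration
#'
#' Gathers every tunable constant of the analysis in one place so a run can
#' be replayed exactly: the fixed SUV threshold (2.5), the relative fraction
#' (40% of SUVmax), the number of histogram clusters (3), the clustering
#' engine and seed, the MTVcsc response cutoff (1.75 cm^3) and its derivation
#' round-up step (0.05 cm^3), and the survival horizon (36 months).
#'
#' @param fixed_threshold SUV, default 2.5.
#' @param relative_fraction fraction of SUVmax in (0, 1), default 0.40.
#' @param k histogram clusters (>= 2), default 3.
#' @param method clustering engine, `"exact-dp"` or `"lloyd"`.
#' @param seed integer seed driving all randomness in a run.
#' @param cutoff MTVcsc response cutoff in cm^3, default 1.75.
#' @param round_up cutoff derivation rounding step in cm^3, default 0.05.
#' @param horizon survival read-out in months, default 36.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fixed_threshold = 2.5, relative_fraction = 0.40,
                            k = 3, method = "exact-dp", seed = 1L,
                            cutoff = 1.75, round_up = 0.05, horizon = 36) {
  if (fixed_threshold <= 0 || cutoff <= 0) stop("thresholds must be > 0")
  if (relative_fraction <= 0 || relative_fraction >= 1)
    stop("relative_fraction must be in (0, 1)")
  if (k < 2) stop("k must be >= 2")
  structure(list(fixed_threshold = fixed_threshold,
                 relative_fraction = relative_fraction, k = k, method = method,
                 seed = as.integer(seed), cutoff = cutoff,
                 round_up = round_up, horizon = horizon),
            class = "pipeline_config")
}

#' Per-lesion parameter extraction for one patient volume
#'
#' Reads a PET SUV volume, applies the FDG-avidity inclusion rule, and for
#' each seeded lesion runs fixed-threshold segmentation, 40%-of-SUVmax
#' segmentation, SUV-histogram clustering and parameter extraction. A
#' non-avid volume (SUVmax below the fixed threshold) is excluded rather
#' than segmented.
#'
#' @param config a [pipeline_config()].
#' @param volume path to a NIfTI volume, or an [suv_volume()].
#' @param seeds list (or single vector) of 0-based seed voxel coordinates,
#'   one per lesion.
#' @param labels lesion labels, recycled against `seeds`.
#' @param patient_id identifier copied into the output rows.
#' @return list with `status` (`"ok"` or `"excluded: non-avid"`) and
#'   `parameters`, a data.frame with one row per lesion (patient_id,
#'   lesion_label, suv_max, mtv, tlg, mtv40, tlg40, mtv_csc, tlg_csc,
#'   csc_proportion).
#' @export
run_lesion <- function(config, volume, seeds, labels = NULL, patient_id = "P0001") {
  stopifnot(inherits(config, "pipeline_config"))
  vol <- if (inherits(volume, "suv_volume")) volume else read_volume(volume)
  if (!check_avidity(vol, config$fixed_threshold))
    return(list(status = "excluded: non-avid", parameters = NULL))
  if (is.null(seeds)) stop("at least one lesion seed voxel is required")
  if (!is.list(seeds)) seeds <- list(seeds)
  if (is.null(labels)) labels <- paste0("lesion", seq_along(seeds))
  rows <- lapply(seq_along(seeds), function(i) {
    voi <- segment_fixed_threshold(vol, seeds[[i]], config$fixed_threshold,
                                   label = labels[[i]])
    voi40 <- segment_relative_threshold(vol, voi, config$relative_fraction)
    part <- cluster_suv_histogram(voi, k = config$k, method = config$method,
                                  seed = config$seed)
    cbind(data.frame(patient_id = patient_id, lesion_label = labels[[i]]),
          conventional_parameters(voi, voi40), csc_parameters(voi, part))
  })
  list(status = "ok", parameters = do.call(rbind, rows))
}

.cohort_columns <- c("patient_id", "age", "histology", "t_stage",
                     "anatomic_stage", "grade", "ki67_pct", "er_status",
                     "her2_status", "subtype", "nac_regimen", "anti_her2_nac",
                     "mtv_csc", "tlg_csc", "csc_proportion", "suv_max", "mtv",
                     "tlg", "mtv40", "tlg40", "pcr", "dfs_months",
                     "relapse_event")

#' Cohort-level statistical reports
#'
#' Runs the full cohort analysis on a table conforming to the cohort schema
#' (see [generate_cohort()]): univariable odds-ratio table and the
#' multivariable ER + MTVcsc logistic model on the HER2-positive/
#' triple-negative subset (the luminal subtype, with no pCR cases, is
#' analysed only for prediction accuracy), cutoff confusion tables with
#' accuracies by subtype / NAC regimen / anti-HER2 exposure, and Kaplan-Meier
#' DFS with a log-rank comparison between the cutoff groups. With zero
#' relapse events the survival stage is skipped with a warning and the other
#' reports complete.
#'
#' @param config a [pipeline_config()].
#' @param cohort cohort data.frame or CSV path.
#' @param out_dir optional directory; when given, every report is also
#'   written as CSV.
#' @return list: `or_table`, `multivariable` (a [logistic_fit()] or NULL),
#'   `accuracy_by_subtype`, `accuracy_by_regimen`, `accuracy_by_anti_her2`,
#'   `km_by_group`, `logrank`, `dfs_at_horizon`, `config`.
#' @export
run_cohort <- function(config, cohort, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ", paste(missing_cols, collapse = ", "))
  cohort$pcr <- as.logical(cohort$pcr)
  cohort$relapse_event <- as.logical(cohort$relapse_event)

  her2tn <- cohort[cohort$subtype %in% c("her2_positive", "triple_negative"), ]
  or_table <- univariable_or_table(her2tn)
  multi <- tryCatch(
    logistic_fit(data.frame(er_negative = her2tn$er_status == "negative",
                            mtv_csc = her2tn$mtv_csc),
                 her2tn$pcr),
    error = function(e) { warning("multivariable fit failed: ", conditionMessage(e)); NULL })

  acc_subtype <- accuracy_by_group(cohort,
                                   ifelse(cohort$subtype == "luminal", "luminal", "her2_tn"),
                                   config$cutoff)
  acc_regimen <- accuracy_by_group(her2tn, "nac_regimen", config$cutoff)
  her2 <- her2tn[her2tn$her2_status == "positive", ]
  acc_her2 <- if (nrow(her2)) accuracy_by_group(her2, "anti_her2_nac", config$cutoff) else NULL

  surv_grp <- ifelse(her2tn$mtv_csc < config$cutoff, "low_mtvcsc", "high_mtvcsc")
  if (sum(her2tn$relapse_event) == 0) {
    warning("no relapse events: skipping the survival comparison")
    km <- lr <- dfs <- NULL
  } else {
    km <- lapply(split(seq_len(nrow(her2tn)), surv_grp), function(i)
      km_estimate(her2tn$dfs_months[i], her2tn$relapse_event[i]))
    lr <- logrank(her2tn$dfs_months, her2tn$relapse_event, surv_grp)
    dfs <- lapply(km, survival_at, t = config$horizon)
  }

  out <- list(or_table = or_table, multivariable = multi,
              accuracy_by_subtype = acc_subtype,
              accuracy_by_regimen = acc_regimen,
              accuracy_by_anti_her2 = acc_her2,
              km_by_group = km, logrank = lr, dfs_at_horizon = dfs,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(or_table, file.path(out_dir, "univariable_or.csv"), row.names = FALSE)
    utils::write.csv(acc_subtype, file.path(out_dir, "accuracy_by_subtype.csv"), row.names = FALSE)
    utils::write.csv(acc_regimen, file.path(out_dir, "accuracy_by_regimen.csv"), row.names = FALSE)
    if (!is.null(acc_her2))
      utils::write.csv(acc_her2, file.path(out_dir, "accuracy_by_anti_her2.csv"), row.names = FALSE)
    if (!is.null(multi))
      utils::write.csv(multi$table, file.path(out_dir, "multivariable_logistic.csv"), row.names = FALSE)
    if (!is.null(km))
      for (g in names(km)) write_km_csv(km[[g]], file.path(out_dir, paste0("km_", g, ".csv")))
  }
  out
}

#' Published contingency counts
#'
#' The cell counts printed in the source study's response-prediction and
#' univariable tables, shipped as plain-text package data so the closed-form
#' statistics (odds ratios, accuracies) can be recomputed from the published
#' counts without patient images. See
#' `system.file("extdata", package = "petcsc")` for the CSV files.
#'
#' @param which `"or"` (2x2 predictor cells) or `"accuracy"` (confusion cells
#'   per subgroup).
#' @return data.frame of counts.
#' @export
published_counts <- function(which = c("or", "accuracy")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("published_", which, "_counts.csv"),
                   package = "petcsc", mustWork = TRUE)
  utils::read.csv(f)
}
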
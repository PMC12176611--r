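#' Configure an end-to-end triage evaluation run
#'
#' @param mode `"simulate"` (generate the cohorts from `cohort_params`) or
#'   `"load"` (read cohort CSV files).
#' @param cohorts For `"simulate"`: a list of [cohort_params()] (default:
#'   the five built-in study cohorts). For `"load"`: a named character
#'   vector of CSV paths.
#' @param derivation_cohort Cohort on which cutoffs are derived; its own
#'   metrics are labelled in-sample.
#' @param markers Marker columns to evaluate. The derived markers
#'   `ptau217_ab42_ratio` (plasma p-tau217 / plasma Ab42) and
#'   `ms_percent_ptau217` (MS p-tau217 / np-tau217 x 100) are computed on
#'   the fly.
#' @param reference A [reference_config()] defining the AD-pathology
#'   reference standard.
#' @param single_specificity,dual_sensitivity,dual_specificity Cutoff
#'   targets.
#' @param youden Also derive and report Youden single cutoffs.
#' @param subgroup_factors Factors for the pooled subgroup analysis of the
#'   first marker (empty vector to skip).
#' @param n_boot Bootstrap iterations for cutoff derivation and hypothesis
#'   tests.
#' @param n_boot_ci Bootstrap iterations for metric CIs (defaults to
#'   `n_boot`).
#' @param seed Global integer seed; every stage draws a deterministic
#'   sub-stream from it.
#' @param output_dir Directory for report CSVs and the manifest (`NULL` to
#'   return results only).
#' @param costs Cost inputs for the triage cost table (see
#'   [default_us_costs()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"), cohorts = NULL,
                       derivation_cohort = "Malmö",
                       markers = c("plasma_ptau217", "ptau217_ab42_ratio",
                                   "ms_ptau217", "ms_percent_ptau217"),
                       reference = reference_config(),
                       single_specificity = 0.90, dual_sensitivity = 0.95,
                       dual_specificity = 0.95, youden = FALSE,
                       subgroup_factors = c("age_band", "sex", "ckd",
                                            "diabetes", "apoe4", "stage"),
                       n_boot = 2000L, n_boot_ci = NULL, seed = 1L,
                       output_dir = NULL, costs = default_us_costs()) {
  mode <- match.arg(mode)
  if (is.null(cohorts)) {
    if (mode == "load") stop("load mode requires cohort file paths",
                             call. = FALSE)
    cohorts <- lapply(study_cohorts(), default_cohort_params)
    names(cohorts) <- study_cohorts()
  }
  if (mode == "simulate" && is.null(names(cohorts))) {
    names(cohorts) <- vapply(cohorts, function(p) p$cohort_name, "")
  }
  if (!derivation_cohort %in% names(cohorts)) {
    stop("derivation cohort '", derivation_cohort,
         "' is not among the configured cohorts: ",
         paste(names(cohorts), collapse = ", "), call. = FALSE)
  }
  structure(
    list(mode = mode, cohorts = cohorts,
         derivation_cohort = derivation_cohort, markers = markers,
         reference = reference, single_specificity = single_specificity,
         dual_sensitivity = dual_sensitivity,
         dual_specificity = dual_specificity, youden = youden,
         subgroup_factors = subgroup_factors, n_boot = as.integer(n_boot),
         n_boot_ci = as.integer(n_boot_ci %||% n_boot),
         seed = as.integer(seed), output_dir = output_dir, costs = costs),
    class = "run_config"
  )
}

# derived ratio markers appended to a cohort tibble
add_derived_markers <- function(cohort) {
  if (all(c("plasma_ptau217", "plasma_ab42") %in% names(cohort))) {
    cohort$ptau217_ab42_ratio <- cohort$plasma_ptau217 / cohort$plasma_ab42
  }
  if (all(c("ms_ptau217", "ms_np_ptau217") %in% names(cohort))) {
    cohort$ms_percent_ptau217 <-
      cohort$ms_ptau217 / cohort$ms_np_ptau217 * 100
  }
  cohort
}

#' Run the full triage evaluation pipeline
#'
#' Simulates or loads the cohorts, derives the AD-pathology reference label
#' (Gaussian-mixture CSF cutoff fitted on all pooled CSF values, with the
#' amyloid-PET fallback), freezes single and dual cutoffs per marker on the
#' derivation cohort, evaluates every cohort out-of-sample under both
#' classification modes, runs marker-vs-marker and primary-vs-secondary
#' comparisons and pooled subgroup analyses, computes the triage cost
#' table, and returns (optionally writes) the report bundle. Deterministic
#' under the configured seed.
#'
#' @param config A [run_config()].
#' @return A list of class `triage_report`: `cohorts`, `gmm`,
#'   `cutoff_sets`, `metrics`, `comparisons`, `subgroups`, `cost`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  cohorts <- if (config$mode == "simulate") {
    lapply(names(config$cohorts), function(nm) {
      generate_cohort(config$cohorts[[nm]],
                      seed = substream_seed(seed, paste0("simulate/", nm)))
    })
  } else {
    lapply(unname(config$cohorts), read_cohort_csv)
  }
  names(cohorts) <- names(config$cohorts)
  cohorts <- lapply(cohorts, add_derived_markers)

  for (nm in names(cohorts)) {
    absent <- setdiff(config$markers, names(cohorts[[nm]]))
    if (length(absent)) {
      stop("cohort '", nm, "' lacks marker columns: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }

  # reference standard: GMM cutoff fitted once on all pooled CSF ratios
  gmm <- NULL
  if (config$reference$outcome == "csf_ab42_ptau181_gmm") {
    pooled_csf <- unlist(lapply(cohorts, function(x) x$csf_ab42_ptau181))
    gmm <- fit_gmm_cutoff(pooled_csf[!is.na(pooled_csf)],
                          seed = substream_seed(seed, "gmm"))
  }
  for (nm in names(cohorts)) {
    cohorts[[nm]]$ref_status <- assign_ad_status(cohorts[[nm]],
                                                 config$reference, gmm)
  }

  deriv <- cohorts[[config$derivation_cohort]]
  deriv_known <- deriv[deriv$ref_status != "unknown", ]
  cutoff_sets <- lapply(setNames(config$markers, config$markers),
                        function(mk) {
    derive_cutoff_set(
      deriv_known[[mk]], deriv_known$ref_status, marker_name = mk,
      derivation_cohort = config$derivation_cohort,
      single_specificity = config$single_specificity,
      dual_sensitivity = config$dual_sensitivity,
      dual_specificity = config$dual_specificity, youden = config$youden,
      n_boot = config$n_boot,
      seed = substream_seed(seed, paste0("cutoffs/", mk)))
  })

  metrics <- list()
  n_unknown <- integer(length(cohorts))
  names(n_unknown) <- names(cohorts)
  for (nm in names(cohorts)) {
    known <- cohorts[[nm]][cohorts[[nm]]$ref_status != "unknown", ]
    n_unknown[nm] <- nrow(cohorts[[nm]]) - nrow(known)
    for (mk in config$markers) {
      for (mode in c("single", "dual")) {
        tb <- metric_table(
          known[[mk]], known$ref_status, cutoff_sets[[mk]], mode,
          n_boot = config$n_boot_ci,
          seed = substream_seed(seed, paste("metrics", nm, mk, mode,
                                            sep = "/")))
        tb$cohort <- nm
        tb$marker <- mk
        tb$mode <- mode
        tb$in_sample <- nm == config$derivation_cohort
        metrics[[length(metrics) + 1]] <- tb
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  metrics <- metrics[, c("cohort", "marker", "mode", "in_sample", "metric",
                         "estimate", "ci_low", "ci_high", "n")]

  pooled <- dplyr::bind_rows(cohorts)
  pooled <- pooled[pooled$ref_status != "unknown", ]

  comparisons <- list()
  ref_marker <- config$markers[1]
  # marker vs marker, paired, on the pooled data
  for (mk in setdiff(config$markers, ref_marker)) {
    dl <- delong_test(pooled[[ref_marker]], pooled[[mk]],
                      truth = pooled$ref_status, paired = TRUE)
    comparisons[[length(comparisons) + 1]] <- tibble::tibble(
      contrast = "marker", group_a = ref_marker, group_b = mk,
      mode = NA_character_, metric = "auc", delta = dl$delta,
      p_value = dl$p_value, method = dl$method)
    for (mode in c("single", "dual")) {
      pred_a <- classify_triage(pooled[[ref_marker]],
                                cutoff_sets[[ref_marker]], mode)
      pred_b <- classify_triage(pooled[[mk]], cutoff_sets[[mk]], mode)
      for (m in c("accuracy",
                  if (mode == "dual") "intermediate_fraction")) {
        bt <- bootstrap_metric_test(
          m, truth_a = pooled$ref_status, pred_a = pred_a, pred_b = pred_b,
          paired = TRUE, n_boot = config$n_boot,
          seed = substream_seed(seed, paste("cmp-marker", mk, mode, m,
                                            sep = "/")))
        comparisons[[length(comparisons) + 1]] <- tibble::tibble(
          contrast = "marker", group_a = ref_marker, group_b = mk,
          mode = mode, metric = m, delta = bt$delta, p_value = bt$p_value,
          method = bt$method)
      }
    }
  }
  # primary vs pooled secondary care, unpaired, first marker
  if (all(c("primary", "secondary") %in% pooled$care_level)) {
    prim <- pooled[pooled$care_level == "primary", ]
    sec <- pooled[pooled$care_level == "secondary", ]
    for (mode in c("single", "dual")) {
      pred_a <- classify_triage(prim[[ref_marker]],
                                cutoff_sets[[ref_marker]], mode)
      pred_b <- classify_triage(sec[[ref_marker]],
                                cutoff_sets[[ref_marker]], mode)
      bt <- bootstrap_metric_test(
        "accuracy", truth_a = prim$ref_status, truth_b = sec$ref_status,
        pred_a = pred_a, pred_b = pred_b, paired = FALSE,
        n_boot = config$n_boot,
        seed = substream_seed(seed, paste0("cmp-care/", mode)))
      comparisons[[length(comparisons) + 1]] <- tibble::tibble(
        contrast = "care_level", group_a = "primary", group_b = "secondary",
        mode = mode, metric = "accuracy", delta = bt$delta,
        p_value = bt$p_value, method = bt$method)
    }
    dl <- delong_test(prim[[ref_marker]], sec[[ref_marker]],
                      truth = prim$ref_status, truth_b = sec$ref_status,
                      paired = FALSE)
    comparisons[[length(comparisons) + 1]] <- tibble::tibble(
      contrast = "care_level", group_a = "primary", group_b = "secondary",
      mode = NA_character_, metric = "auc", delta = dl$delta,
      p_value = dl$p_value, method = dl$method)
  }
  comparisons <- dplyr::bind_rows(comparisons)

  subgroups <- list()
  for (fac in config$subgroup_factors) {
    for (mode in c("single", "dual")) {
      sg <- subgroup_analysis(
        pooled, ref_marker, cutoff_sets[[ref_marker]], fac, mode,
        truth_col = "ref_status", n_boot = config$n_boot,
        seed = substream_seed(seed, paste("subgroup", fac, mode,
                                          sep = "/")),
        ci = TRUE)
      sg$metrics$factor <- fac
      sg$metrics$mode <- mode
      sg$comparisons$factor <- if (nrow(sg$comparisons)) fac else character()
      sg$comparisons$mode <- if (nrow(sg$comparisons)) mode else character()
      subgroups[[length(subgroups) + 1]] <- sg
    }
  }
  subgroup_metrics <- dplyr::bind_rows(lapply(subgroups, `[[`, "metrics"))
  subgroup_comparisons <- dplyr::bind_rows(lapply(subgroups, `[[`,
                                                  "comparisons"))

  # pooled intermediate fraction of the first marker drives the cost table
  pooled_pred <- classify_triage(pooled[[ref_marker]],
                                 cutoff_sets[[ref_marker]], "dual")
  p_int <- mean(pooled_pred == "intermediate", na.rm = TRUE)
  cost <- savings_table(config$costs$cost_plasma, config$costs$cost_csf,
                        config$costs$cost_pet, p_intermediate = p_int,
                        confirmatory = config$costs$confirmatory)

  manifest <- list(
    package_version = as.character(utils::packageVersion("adtriage")),
    seed = seed, mode = config$mode, cohorts = names(cohorts),
    n_subjects = vapply(cohorts, nrow, 0L),
    n_unknown_reference = n_unknown,
    derivation_cohort = config$derivation_cohort,
    markers = config$markers,
    reference_outcome = config$reference$outcome,
    gmm_cutoff = if (!is.null(gmm)) gmm$cutoff else NA_real_,
    n_boot = config$n_boot, n_boot_ci = config$n_boot_ci,
    pooled_intermediate_fraction = p_int,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  report <- structure(
    list(cohorts = cohorts, gmm = gmm, cutoff_sets = cutoff_sets,
         metrics = metrics, comparisons = comparisons,
         subgroups = list(metrics = subgroup_metrics,
                          comparisons = subgroup_comparisons),
         cost = cost, manifest = manifest),
    class = "triage_report"
  )
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  report
}

#' Write a pipeline report bundle to a directory
#'
#' @param report A `triage_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "triage_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"))
  readr::write_csv(report$subgroups$metrics,
                   file.path(dir, "subgroup_metrics.csv"))
  readr::write_csv(report$subgroups$comparisons,
                   file.path(dir, "subgroup_comparisons.csv"))
  readr::write_csv(report$cost, file.path(dir, "cost.csv"))
  for (mk in names(report$cutoff_sets)) {
    write_cutoff_set(report$cutoff_sets[[mk]],
                     file.path(dir, paste0("cutoffs_", mk, ".json")))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Triage evaluation report\n")
  cat("  cohorts:", paste(x$manifest$cohorts, collapse = ", "), "\n")
  cat("  derivation:", x$manifest$derivation_cohort, "\n")
  if (!is.na(x$manifest$gmm_cutoff)) {
    cat(sprintf("  reference GMM cutoff: %.3f\n", x$manifest$gmm_cutoff))
  }
  cat(sprintf("  pooled intermediate fraction: %.1f%%\n",
              100 * x$manifest$pooled_intermediate_fraction))
  cat("  metric rows:", nrow(x$metrics), "\n")
  invisible(x)
}
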
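#' Run the full subtype-and-stage analysis pipeline
#'
#' Orchestrates every stage end-to-end: amyloid cut-point estimation from the
#' pooled CSF amyloid values, selection of the reference-control and case
#' groups, completeness filtering, control-referenced normalisation,
#' cross-validated choice of the number of subtypes (optional), the final
#' model fit, per-subject assignment, positional variance diagrams, and the
#' post-hoc evaluation tables. Fully deterministic for a fixed seed; every
#' stage draws from its own substream of the root seed.
#'
#' @param config list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{cohort}{a [cohort()], a data frame, or a CSV path for
#'       [load_cohort()]; pooled controls + cases.}
#'     \item{panel}{optional [marker_panel()] (default
#'       [default_marker_panel()]).}
#'     \item{settings}{optional [sustain_settings()] or list of its
#'       arguments.}
#'     \item{n_subtypes}{fixed number of subtypes; omit to select by CVIC.}
#'     \item{max_subtypes}{largest C for CVIC selection (default 4).}
#'     \item{run_crossval}{logical; run CVIC selection (default `TRUE` when
#'       `n_subtypes` is missing).}
#'     \item{cutpoint_percentile}{mixture quantile for the cut-point
#'       (default 0.99).}
#'     \item{seed}{root seed overriding `settings$seed`.}
#'     \item{out_dir}{optional directory for CSV/JSON artefacts.}
#'   }
#' @return list of class `amypath_run`: `report` (counts, cut-point, CVIC
#'   table, selected C, group sizes, file manifest) plus the fitted objects
#'   (`cutpoint`, `reference`, `zmatrix`, `cvic`, `model`, `assignments`,
#'   `pvd`, `summary`, `progression`).
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))

  x <- config$cohort
  if (is.character(x)) x <- load_cohort(x)
  if (is.data.frame(x)) x <- as_cohort_df(x)
  if (!inherits(x, "cohort")) stop("config$cohort must be a cohort, data frame or CSV path")
  panel <- config$panel %||% default_marker_panel()
  settings <- config$settings %||% sustain_settings()
  if (!inherits(settings, "sustain_settings"))
    settings <- do.call(sustain_settings, settings)
  if (!is.null(config$seed)) settings$seed <- as.integer(config$seed)

  # 1. amyloid gate
  fit <- fit_gmm_1d(x$subjects$csf_abeta, seed = settings$seed)
  cutpoint <- derive_cutpoint(fit, percentile = config$cutpoint_percentile %||% 0.99)

  # 2. group selection + completeness
  controls <- select_reference_controls(x, cutpoint)
  cases <- select_cases(x, cutpoint)
  cc <- apply_completeness_filter(controls)
  cx <- apply_completeness_filter(cases)
  controls <- cc$cohort
  cases <- cx$cohort

  # 3. normalisation
  reference <- fit_control_reference(controls, panel)
  Z <- build_zscore_matrix(cases, reference, panel)

  # 4. model selection
  cvic <- NULL
  run_cv <- config$run_crossval %||% is.null(config$n_subtypes)
  if (isTRUE(run_cv)) {
    cvic <- cross_validate_cvic(Z, panel,
                                max_subtypes = config$max_subtypes %||%
                                  settings$max_subtypes,
                                settings = settings)
  }
  n_subtypes <- config$n_subtypes %||% cvic$selected

  # 5. fit, assign, visualise, evaluate
  model <- fit_sustain(Z, panel, n_subtypes, settings)
  assignments <- assign_subjects(Z, model)
  pvd <- positional_variance(model, assignments)
  summary_tab <- summarize_groups(cases, assignments)
  progression <- progression_summary(cases, assignments)

  group_sizes <- as.integer(summary_tab$n)
  names(group_sizes) <- names(summary_tab$n)
  report <- list(
    seed = settings$seed,
    n_input = n_subjects(x),
    n_controls = n_subjects(controls),
    n_cases = n_subjects(cases),
    n_excluded_incomplete = nrow(cc$excluded) + nrow(cx$excluded),
    cutpoint = cutpoint$value,
    cvic = if (!is.null(cvic)) cvic$cvic,
    selected_subtypes = n_subtypes,
    group_sizes = group_sizes,
    loglik = model$loglik)

  out <- structure(list(report = report, cutpoint = cutpoint,
                        reference = reference, zmatrix = Z, cvic = cvic,
                        model = model, assignments = assignments, pvd = pvd,
                        summary = summary_tab, progression = progression),
                   class = "amypath_run")
  if (!is.null(config$out_dir)) .write_run_artifacts(out, config$out_dir)
  out
}

.write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  wr <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest <<- c(manifest, path)
  }
  wr(data.frame(subject_id = rownames(run$zmatrix),
                as.data.frame(unclass(run$zmatrix))), "zscores.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  wr(as.data.frame(run$assignments), "assignments.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  for (k in seq_along(run$pvd)) {
    wr(run$pvd[[k]]$P, sprintf("pvd_subtype%d.csv", k),
       function(o, p) utils::write.csv(o, p))
  }
  report <- run$report
  report$manifest <- manifest
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.amypath_run <- function(x, ...) {
  r <- x$report
  cat("<amypath_run> seed", r$seed, "\n")
  cat(sprintf("  input %d -> controls %d, cases %d (%d incomplete excluded)\n",
              r$n_input, r$n_controls, r$n_cases, r$n_excluded_incomplete))
  cat(sprintf("  amyloid cut-point %.1f pg/mL; %d subtype(s) selected\n",
              r$cutpoint, r$selected_subtypes))
  cat("  group sizes:", paste(names(r$group_sizes), r$group_sizes,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}
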
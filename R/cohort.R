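#' @title Cohort container
#' @description A `cohort` wraps a per-subject data frame together with the
#'   group role it plays in the analysis (`"reference_controls"`, `"cases"`,
#'   or `"unassigned"`) and free-text provenance. Follow-up diagnoses are kept
#'   in a list column `followup`, each element a data frame with columns
#'   `month` and `diagnosis`.
#'
#' @param subjects data frame of subject records.
#' @param role group role of the cohort.
#' @param provenance free-text origin note.
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, role = c("unassigned", "reference_controls", "cases"),
                   provenance = "") {
  role <- match.arg(role)
  stopifnot(is.data.frame(subjects))
  if (nrow(subjects) > 0) {
    if (!"subject_id" %in% names(subjects)) stop("subjects need a subject_id column")
    if (anyDuplicated(subjects$subject_id))
      stop("duplicate subject_id: ",
           paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
                 collapse = ", "))
  }
  structure(list(subjects = subjects, role = role, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> role=", x$role, ", n=", nrow(x$subjects), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x a [cohort()].
#' @export
n_subjects <- function(x) nrow(x$subjects)

.diagnosis_levels <- c("CN", "SMC", "MCI", "AD")

# required per-subject analysis fields; a subject missing any is incomplete
.required_fields <- c("csf_abeta", "csf_ptau181", "wmh_ml", "wbv_ml", "hip_ml",
                      "tiv_ml", "lm_score", "tmt_a_s", "tmt_b_s")

.default_columns <- c("subject_id", "baseline_diagnosis", "age_years", "sex",
                      "apoe_e4_carrier", "education_years", "csf_abeta",
                      "csf_ptau181", "wmh_ml", "wbv_ml", "hip_ml", "tiv_ml",
                      "lm_score", "tmt_a_s", "tmt_b_s", "hypertension",
                      "stroke", "lacune_present", "cmb_present", "followup")

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}

# follow-up visits serialised as "6:CN;12:CN;24:MCI"
.parse_followup <- function(x) {
  lapply(x, function(s) {
    if (is.null(s) || is.na(s) || !nzchar(trimws(s)))
      return(data.frame(month = integer(0), diagnosis = character(0)))
    parts <- strsplit(strsplit(trimws(s), ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed followup entry: ", s)
    df <- data.frame(month = as.integer(vapply(parts, `[`, "", 1L)),
                     diagnosis = trimws(vapply(parts, `[`, "", 2L)))
    if (any(!df$diagnosis %in% .diagnosis_levels))
      stop("unknown follow-up diagnosis in: ", s)
    df[order(df$month), , drop = FALSE]
  })
}

.format_followup <- function(fu) {
  vapply(fu, function(df) {
    if (is.null(df) || nrow(df) == 0) return("")
    paste(paste0(df$month, ":", df$diagnosis), collapse = ";")
  }, "")
}

#' Load a cohort table from CSV
#'
#' Reads a comma-separated, UTF-8, headered file; empty cells and `"NA"` are
#' treated as missing. Columns can be renamed through `column_map`
#' (`list(internal_name = "file column")`). The TMT-B completion-time ceiling
#' of 300 s is applied on load and recorded in the logical column
#' `tmt_b_ceiling`; the derived composite TMT column `tmt_comp` is added (see
#' [composite_tmt()]). Rows with unparseable or missing required fields are
#' kept and flagged, never silently dropped — use
#' [apply_completeness_filter()] to exclude them explicitly.
#'
#' @param path CSV file path.
#' @param column_map optional named list/character vector mapping internal
#'   column names to the file's column names.
#' @return A [cohort()] with role `"unassigned"`.
#' @export
load_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src))
      stop("mapped column(s) absent from file: ", paste(missing_src, collapse = ", "))
    for (internal in names(column_map)) {
      names(raw)[names(raw) == column_map[[internal]]] <- internal
    }
  }
  missing_cols <- setdiff(c("subject_id", .required_fields), names(raw))
  if (length(missing_cols))
    stop("required column(s) missing: ", paste(missing_cols, collapse = ", "))
  as_cohort_df(raw, provenance = paste0("loaded from ", path))
}

#' Build a cohort from an in-memory data frame
#'
#' Applies the same typing, TMT-B ceiling and composite-TMT derivation as
#' [load_cohort()].
#'
#' @param df data frame with cohort columns.
#' @param role cohort role.
#' @param provenance free-text origin note.
#' @return A [cohort()].
#' @export
as_cohort_df <- function(df, role = "unassigned", provenance = "in-memory") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  num_cols <- c("age_years", "education_years", .required_fields)
  for (cc in intersect(num_cols, names(df))) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  for (cc in intersect(c("apoe_e4_carrier", "hypertension", "stroke",
                         "lacune_present", "cmb_present"), names(df))) {
    df[[cc]] <- .parse_logical(df[[cc]])
  }
  if ("baseline_diagnosis" %in% names(df) &&
      any(!is.na(df$baseline_diagnosis) &
          !df$baseline_diagnosis %in% .diagnosis_levels))
    stop("unknown baseline diagnosis value(s)")
  if ("followup" %in% names(df) && !is.list(df$followup)) {
    df$followup <- .parse_followup(df$followup)
  } else if (!"followup" %in% names(df)) {
    df$followup <- .parse_followup(rep(NA_character_, nrow(df)))
  }
  # TMT-B ceiling: times of 300 s or more are censored at 300 and flagged
  if ("tmt_b_s" %in% names(df)) {
    df$tmt_b_ceiling <- !is.na(df$tmt_b_s) & df$tmt_b_s >= 300
    df$tmt_b_s <- pmin(df$tmt_b_s, 300)
  }
  if (all(c("tmt_a_s", "tmt_b_s") %in% names(df))) {
    df$tmt_comp <- ifelse(is.na(df$tmt_a_s) | is.na(df$tmt_b_s), NA_real_,
                          mapply(function(a, b) {
                            if (is.na(a) || is.na(b)) NA_real_ else composite_tmt(a, b)
                          }, df$tmt_a_s, df$tmt_b_s))
  }
  cohort(df, role = "unassigned", provenance = provenance)
}

#' Exclude subjects with missing required marker data
#'
#' Retains subjects with a complete set of the analysis fields (CSF amyloid
#' and p-tau, WMH/whole-brain/hippocampal/intracranial volumes, logical
#' memory, TMT A and B); everyone else is returned as an exclusion record
#' with the missing fields named.
#'
#' @param x a [cohort()].
#' @return list with `cohort` (complete subjects, same role) and `excluded`
#'   (data frame of `subject_id`, `reason`).
#' @export
apply_completeness_filter <- function(x) {
  stopifnot(inherits(x, "cohort"))
  df <- x$subjects
  if (nrow(df) == 0)
    return(list(cohort = x, excluded = data.frame(subject_id = character(0),
                                                  reason = character(0))))
  miss <- sapply(.required_fields, function(f) is.na(df[[f]]))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = 1)
  incomplete <- rowSums(miss) > 0
  excluded <- data.frame(
    subject_id = df$subject_id[incomplete],
    reason = apply(miss[incomplete, , drop = FALSE], 1, function(r)
      paste0("missing: ", paste(.required_fields[r], collapse = ", "))))
  if (all(incomplete)) warning("no complete subjects remain")
  out <- x
  out$subjects <- df[!incomplete, , drop = FALSE]
  list(cohort = out, excluded = excluded)
}

#' Select the amyloid-negative reference control group
#'
#' Controls define the z-score reference and must be CSF amyloid negative
#' (value above the cut-point; equality counts as negative), APOE e4
#' non-carriers, cognitively normal at baseline (subjective-memory-concern
#' labels count as CN), and diagnostically CN at every recorded follow-up
#' visit. Subjects without follow-up visits are treated as stable.
#'
#' @param x a [cohort()].
#' @param cutpoint a [derive_cutpoint()] result, or a single numeric pg/mL
#'   value.
#' @return A [cohort()] with role `"reference_controls"`.
#' @export
select_reference_controls <- function(x, cutpoint) {
  stopifnot(inherits(x, "cohort"))
  cut <- .cutpoint_value(cutpoint)
  df <- x$subjects
  if (nrow(df) == 0) return(cohort(df, "reference_controls", x$provenance))
  stable_cn <- vapply(df$followup, function(fu)
    nrow(fu) == 0 || all(fu$diagnosis %in% c("CN", "SMC")), TRUE)
  keep <- !is.na(df$csf_abeta) & df$csf_abeta >= cut &
    !is.na(df$apoe_e4_carrier) & !df$apoe_e4_carrier &
    !is.na(df$baseline_diagnosis) & df$baseline_diagnosis %in% c("CN", "SMC") &
    stable_cn
  if (!any(keep)) warning("no subjects meet the reference-control criteria")
  cohort(df[keep, , drop = FALSE], "reference_controls", x$provenance)
}

#' Select the amyloid-positive case group
#'
#' Cases are subjects with CSF amyloid strictly below the cut-point,
#' regardless of baseline or follow-up diagnosis.
#'
#' @inheritParams select_reference_controls
#' @return A [cohort()] with role `"cases"`.
#' @export
select_cases <- function(x, cutpoint) {
  stopifnot(inherits(x, "cohort"))
  cut <- .cutpoint_value(cutpoint)
  df <- x$subjects
  keep <- !is.na(df$csf_abeta) & df$csf_abeta < cut
  if (nrow(df) > 0 && !any(keep)) warning("no amyloid-positive cases found")
  cohort(df[keep, , drop = FALSE], "cases", x$provenance)
}

.cutpoint_value <- function(cutpoint) {
  v <- if (inherits(cutpoint, "amyloid_cutpoint")) cutpoint$value else as.numeric(cutpoint)
  if (length(v) != 1 || !is.finite(v)) stop("cut-point must be a single finite value")
  v
}

#' Write a cohort back to CSV
#'
#' Serialises the follow-up list column to `month:diagnosis` pairs so the file
#' round-trips through [load_cohort()].
#'
#' @param x a [cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- x$subjects
  if ("followup" %in% names(df)) df$followup <- .format_followup(df$followup)
  df$tmt_comp <- NULL
  df$tmt_b_ceiling <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
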
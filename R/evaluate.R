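#' Descriptive summary of assigned groups
#'
#' Tabulates the unsubtyped group and each subtype: group size, mean (SD) for
#' continuous variables — except WMH volume, summarised as median (IQR) given
#' its skew — and count (percent) for categorical/logical variables.
#'
#' @param cases a [cohort()] of the subjects that were assigned.
#' @param assignments an [assign_subjects()] result aligned with `cases`.
#' @param continuous continuous variable columns to summarise.
#' @param categorical logical/categorical columns to summarise.
#' @return list of class `subtype_summary`: `n` (named group sizes),
#'   `continuous` (long data frame: group, variable, stat, value),
#'   `categorical` (group, variable, level, count, percent).
#' @export
summarize_groups <- function(cases, assignments,
                             continuous = c("age_years", "education_years",
                                            "lm_score", "tmt_comp",
                                            "csf_ptau181", "wmh_ml", "wbv_ml",
                                            "hip_ml", "tiv_ml"),
                             categorical = c("baseline_diagnosis", "sex",
                                             "apoe_e4_carrier", "hypertension",
                                             "stroke", "lacune_present",
                                             "cmb_present")) {
  df <- cases$subjects
  stopifnot(nrow(df) == nrow(assignments))
  group <- ifelse(assignments$unsubtyped, "unsubtyped",
                  paste0("subtype", assignments$ml_subtype))
  C <- max(c(0L, assignments$ml_subtype), na.rm = TRUE)
  levels_g <- c("unsubtyped", if (C > 0) paste0("subtype", seq_len(C)))
  group <- factor(group, levels = levels_g)

  n <- table(group)
  cont <- do.call(rbind, lapply(intersect(continuous, names(df)), function(v) {
    do.call(rbind, lapply(levels_g, function(g) {
      x <- df[[v]][group == g]
      x <- x[!is.na(x)]
      if (v == "wmh_ml") {
        data.frame(group = g, variable = v,
                   stat = c("median", "iqr"),
                   value = if (length(x)) c(stats::median(x), stats::IQR(x))
                           else c(NA_real_, NA_real_))
      } else {
        data.frame(group = g, variable = v, stat = c("mean", "sd"),
                   value = if (length(x)) c(mean(x), stats::sd(x))
                           else c(NA_real_, NA_real_))
      }
    }))
  }))
  cat_tab <- do.call(rbind, lapply(intersect(categorical, names(df)), function(v) {
    x <- df[[v]]
    if (is.logical(x)) x <- factor(x, levels = c(FALSE, TRUE),
                                   labels = c("no", "yes"))
    do.call(rbind, lapply(levels_g, function(g) {
      xg <- x[group == g]
      tt <- table(xg)
      data.frame(group = g, variable = v, level = names(tt),
                 count = as.integer(tt),
                 percent = if (sum(tt)) 100 * as.integer(tt) / sum(tt) else NA_real_)
    }))
  }))
  structure(list(n = n, continuous = cont, categorical = cat_tab,
                 group = group),
            class = "subtype_summary")
}

#' @export
print.subtype_summary <- function(x, ...) {
  cat("<subtype_summary>\n")
  print(x$n)
  invisible(x)
}

#' Group contrasts for continuous or categorical variables
#'
#' Continuous variables are compared across groups with a one-way linear
#' regression on group membership (overall F-test); categorical variables
#' with a two-sided Fisher exact test (exact enumeration for small tables,
#' seeded Monte Carlo for larger ones).
#'
#' @param values for `"continuous"`, a list of numeric vectors (one per
#'   group); for `"categorical"`, a contingency table or matrix
#'   (groups x levels).
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param seed seed for the Monte Carlo Fisher fallback.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values, variable_kind = c("continuous", "categorical"),
                           seed = 1L) {
  variable_kind <- match.arg(variable_kind)
  if (variable_kind == "continuous") {
    stopifnot(is.list(values), length(values) >= 2)
    y <- unlist(values, use.names = FALSE)
    g <- factor(rep(seq_along(values), lengths(values)))
    if (stats::var(y) == 0) stop("all values identical; contrast is degenerate")
    fit <- stats::lm(y ~ g)
    a <- stats::anova(fit)
    list(statistic = a[["F value"]][1], p_value = a[["Pr(>F)"]][1],
         method = "linear regression (overall F)")
  } else {
    tab <- as.matrix(values)
    if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
    big <- sum(tab) > 400 || prod(dim(tab)) > 12
    if (big) {
      set.seed(.substream(seed, "fisher"))
      ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)
    } else {
      ft <- stats::fisher.test(tab)
    }
    list(statistic = unname(if (!is.null(ft$estimate)) ft$estimate else NA_real_),
         p_value = ft$p.value,
         method = paste0("Fisher exact (two-sided",
                         if (big) ", Monte Carlo", ")"))
  }
}

#' Marker-stage correlation within a subtype
#'
#' Pairwise Pearson correlation between a marker and the maximum-likelihood
#' stage of the subjects assigned to one subtype, or a semi-partial
#' correlation where the marker is first residualised on an adjustment
#' covariate (total intracranial volume for the volumetric markers; a binary
#' part-B-ceiling indicator for the composite TMT) and the residual is
#' correlated with stage.
#'
#' @param assignments an [assign_subjects()] result.
#' @param data data frame aligned with `assignments` holding marker and
#'   covariate columns (raw or z scale).
#' @param subtype subtype index.
#' @param marker marker column name.
#' @param adjustment optional covariate column name for the semi-partial
#'   variant.
#' @return list of class `stage_correlation`: `subtype`, `marker`,
#'   `coefficient`, `p_value`, `kind`, `adjustment`, `n`.
#' @export
stage_marker_correlation <- function(assignments, data, subtype, marker,
                                     adjustment = NULL) {
  stopifnot(nrow(data) == nrow(assignments))
  rows <- which(!is.na(assignments$ml_subtype) &
                  assignments$ml_subtype == subtype)
  if (length(rows) < 3) stop("need at least 3 subjects in the subtype")
  stage <- assignments$ml_stage[rows]
  x <- data[[marker]][rows]
  ok <- !is.na(x) & !is.na(stage)
  x <- x[ok]; stage <- stage[ok]
  if (stats::var(stage) == 0) stop("constant stage within subtype")
  if (stats::var(x) == 0) stop("constant marker within subtype")
  kind <- "pairwise"
  if (!is.null(adjustment)) {
    cv <- as.numeric(data[[adjustment]][rows][ok])
    res <- stats::resid(stats::lm(x ~ cv))
    if (stats::var(res) < 1e-12)
      stop("marker fully explained by adjustment covariate")
    x <- res
    kind <- "semi_partial"
  }
  ct <- stats::cor.test(x, stage, method = "pearson")
  structure(list(subtype = subtype, marker = marker,
                 coefficient = unname(ct$estimate), p_value = ct$p.value,
                 kind = kind, adjustment = adjustment, n = length(x)),
            class = "stage_correlation")
}

#' @export
print.stage_correlation <- function(x, ...) {
  cat(sprintf("<stage_correlation> subtype %d, %s (%s%s): r = %.3f, p = %.3g, n = %d\n",
              x$subtype, x$marker, x$kind,
              if (!is.null(x$adjustment)) paste0(" | ", x$adjustment) else "",
              x$coefficient, x$p_value, x$n))
  invisible(x)
}

.dx_rank <- c(CN = 1L, SMC = 1L, MCI = 2L, AD = 3L)

#' Diagnostic progression within a follow-up horizon
#'
#' For each group (unsubtyped + subtypes) and baseline diagnosis (CN or MCI;
#' subjective-memory-concern labels count as CN), classifies every subject by
#' the worst diagnosis recorded at follow-up visits within the horizon:
#' `progressed` when the worst exceeds baseline, `reverted` when it is
#' milder, `stable` otherwise, and `missing` with no visit inside the
#' horizon. Groups are compared on progressed-vs-not proportions with a
#' two-sided Fisher exact test.
#'
#' @param cases a [cohort()] with follow-up diagnoses.
#' @param assignments an [assign_subjects()] result aligned with `cases`.
#' @param horizon_months follow-up horizon (default 24).
#' @return list of class `progression_table`: `table` (group, baseline_dx,
#'   stable/progressed/reverted/missing counts) and `fisher` (per baseline
#'   diagnosis, the progressed-vs-not test across groups).
#' @export
progression_summary <- function(cases, assignments, horizon_months = 24L) {
  df <- cases$subjects
  stopifnot(nrow(df) == nrow(assignments))
  group <- ifelse(assignments$unsubtyped, "unsubtyped",
                  paste0("subtype", assignments$ml_subtype))
  C <- max(c(0L, assignments$ml_subtype), na.rm = TRUE)
  levels_g <- c("unsubtyped", if (C > 0) paste0("subtype", seq_len(C)))

  classify <- function(i) {
    base <- .dx_rank[[df$baseline_diagnosis[i]]]
    fu <- df$followup[[i]]
    fu <- fu[fu$month <= horizon_months, , drop = FALSE]
    if (nrow(fu) == 0) return("missing")
    worst <- max(.dx_rank[fu$diagnosis])
    if (worst > base) "progressed" else if (worst < base) "reverted" else "stable"
  }
  base_dx <- ifelse(df$baseline_diagnosis %in% c("CN", "SMC"), "CN",
                    df$baseline_diagnosis)
  status <- vapply(seq_len(nrow(df)), classify, "")

  cells <- expand.grid(group = levels_g, baseline_dx = c("CN", "MCI"),
                       stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
    sel <- group == cells$group[j] & base_dx == cells$baseline_dx[j]
    data.frame(group = cells$group[j], baseline_dx = cells$baseline_dx[j],
               stable = sum(status[sel] == "stable"),
               progressed = sum(status[sel] == "progressed"),
               reverted = sum(status[sel] == "reverted"),
               missing = sum(status[sel] == "missing"))
  }))
  fisher <- lapply(c(CN = "CN", MCI = "MCI"), function(dx) {
    sub <- tab[tab$baseline_dx == dx, ]
    m <- cbind(progressed = sub$progressed,
               not_progressed = sub$stable + sub$reverted)
    rownames(m) <- sub$group
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) < 2) return(NULL)
    compare_groups(m, "categorical")
  })
  structure(list(table = tab, fisher = fisher, status = status,
                 horizon_months = horizon_months),
            class = "progression_table")
}

#' @export
print.progression_table <- function(x, ...) {
  cat("<progression_table> horizon", x$horizon_months, "months\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
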
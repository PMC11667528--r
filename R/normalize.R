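#' Composite Trail Making Test score
#'
#' TMT part B completion time, censored at the 300 s task ceiling, minus part
#' A time. Subtracting part A is intended to isolate executive set-shifting
#' from the shared visuoperceptual and motor demands of the two parts.
#'
#' @param tmt_a_s part A completion time, seconds (> 0).
#' @param tmt_b_s part B completion time, seconds (> 0); values of 300 s or
#'   more are censored at the ceiling.
#' @return composite score in seconds, with attribute `ceiling` marking
#'   whether the part-B ceiling was hit (carried for the ceiling-adjusted
#'   semi-partial correlation in subtype evaluation).
#' @examples
#' composite_tmt(40.8, 112.1)  # 71.3
#' @export
composite_tmt <- function(tmt_a_s, tmt_b_s) {
  if (!is.finite(tmt_a_s) || !is.finite(tmt_b_s) || tmt_a_s <= 0 || tmt_b_s <= 0)
    stop("TMT times must be positive and finite")
  ceiling_hit <- tmt_b_s >= 300
  structure(min(tmt_b_s, 300) - tmt_a_s, ceiling = ceiling_hit)
}

# transformed, direction-aligned value of one marker for a vector of subjects
.aligned_value <- function(df, marker, wmh_offset = 0.01) {
  x <- df[[marker$column]]
  if (marker$transform == "log2") {
    if (any(!is.na(x) & x < 0)) stop("negative value for log2 marker ", marker$name)
    x <- log2(ifelse(!is.na(x) & x == 0, x + wmh_offset, x))
  }
  if (marker$direction == "lower_is_worse") x <- -x
  x
}

#' Fit the control-group normalisation reference
#'
#' Estimates, in amyloid-negative controls only, the location and scale used
#' to z-score each marker on its transformed, direction-aligned scale. Plain
#' markers get a mean and SD; covariate-adjusted markers get an ordinary
#' least-squares regression on the covariate with residual SD on n - 2
#' degrees of freedom (a W-score reference). Cases never contribute to the
#' reference.
#'
#' @param controls a [cohort()] of complete reference controls (>= 10
#'   subjects).
#' @param panel a [marker_panel()].
#' @param wmh_offset volume in mL added to zero WMH measurements before the
#'   log2 transform.
#' @return An object of class `control_reference`.
#' @export
fit_control_reference <- function(controls, panel, wmh_offset = 0.01) {
  stopifnot(inherits(controls, "cohort"), inherits(panel, "marker_panel"))
  df <- controls$subjects
  if (nrow(df) < 10) stop("need at least 10 control subjects")
  refs <- vector("list", n_markers(panel))
  names(refs) <- panel$markers$name
  for (i in seq_len(n_markers(panel))) {
    marker <- panel$markers[i, ]
    y <- .aligned_value(df, marker, wmh_offset)
    if (any(is.na(y))) stop("missing control value for marker ", marker$name)
    tol <- 1e-10 * (abs(mean(y)) + 1)
    if (is.na(marker$covariate)) {
      s <- stats::sd(y)
      if (s < tol) stop("zero control variance for marker ", marker$name)
      refs[[i]] <- list(type = "plain", mean = mean(y), sd = s)
    } else {
      cv <- df[[marker$covariate]]
      if (any(is.na(cv))) stop("missing covariate for marker ", marker$name)
      fit <- stats::lm(y ~ cv)
      resid_sd <- sqrt(sum(stats::resid(fit)^2) / (length(y) - 2))
      if (resid_sd < tol) stop("zero residual variance for marker ", marker$name)
      refs[[i]] <- list(type = "adjusted", covariate = marker$covariate,
                        intercept = unname(stats::coef(fit)[1]),
                        slope = unname(stats::coef(fit)[2]),
                        resid_sd = resid_sd)
    }
  }
  structure(list(markers = refs, n_controls = nrow(df),
                 wmh_offset = wmh_offset),
            class = "control_reference")
}

#' @export
print.control_reference <- function(x, ...) {
  cat("<control_reference> fitted on", x$n_controls, "controls\n")
  for (nm in names(x$markers)) {
    r <- x$markers[[nm]]
    if (r$type == "plain") {
      cat(sprintf("  %-5s mean %8.3f  sd %7.3f\n", nm, r$mean, r$sd))
    } else {
      cat(sprintf("  %-5s ~ %s: intercept %8.3f  slope %8.5f  resid sd %7.3f\n",
                  nm, r$covariate, r$intercept, r$slope, r$resid_sd))
    }
  }
  invisible(x)
}

#' Z-score one subject against the control reference
#'
#' Applies the marker transform and direction alignment, then standardises:
#' plain markers as `(x - mean) / sd`, covariate-adjusted markers as the
#' W-score `(x - (intercept + slope * covariate)) / resid_sd`. Higher z
#' always means more abnormal.
#'
#' @param record single-row data frame (one subject, all panel columns).
#' @param ref a [fit_control_reference()] result.
#' @param panel a [marker_panel()].
#' @return named numeric vector of z values, one per panel marker.
#' @export
zscore_subject <- function(record, ref, panel) {
  stopifnot(nrow(record) == 1)
  z <- numeric(n_markers(panel))
  names(z) <- panel$markers$name
  for (i in seq_len(n_markers(panel))) {
    marker <- panel$markers[i, ]
    r <- ref$markers[[marker$name]]
    y <- .aligned_value(record, marker, ref$wmh_offset)
    z[i] <- if (r$type == "plain") {
      (y - r$mean) / r$sd
    } else {
      (y - (r$intercept + r$slope * record[[r$covariate]])) / r$resid_sd
    }
  }
  z
}

#' Build the case z-score matrix
#'
#' Produces the subjects-by-markers matrix of direction-aligned,
#' control-referenced z-scores that is the sole input to the subtype-and-stage
#' model.
#'
#' @param cases a [cohort()] of complete subjects.
#' @param ref a [fit_control_reference()] result.
#' @param panel a [marker_panel()].
#' @return numeric matrix with subject ids as row names and marker names as
#'   columns, of class `zscore_matrix`.
#' @export
build_zscore_matrix <- function(cases, ref, panel) {
  stopifnot(inherits(cases, "cohort"))
  df <- cases$subjects
  Z <- matrix(NA_real_, nrow(df), n_markers(panel),
              dimnames = list(df$subject_id, panel$markers$name))
  for (i in seq_len(n_markers(panel))) {
    marker <- panel$markers[i, ]
    r <- ref$markers[[marker$name]]
    y <- .aligned_value(df, marker, ref$wmh_offset)
    Z[, i] <- if (r$type == "plain") {
      (y - r$mean) / r$sd
    } else {
      (y - (r$intercept + r$slope * df[[r$covariate]])) / r$resid_sd
    }
  }
  if (nrow(Z) > 0 && any(is.na(Z)))
    stop("missing z-score entries; run apply_completeness_filter() first")
  class(Z) <- c("zscore_matrix", class(Z))
  Z
}
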
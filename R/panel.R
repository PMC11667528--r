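#' Declarative biomarker panel
#'
#' A `marker_panel` describes, for each modelled biomarker, the direction of
#' abnormality, an optional variance-stabilising transform, an optional
#' head-size covariate adjustment, the z-score thresholds at which discrete
#' progression events are placed, and the trajectory ceiling `z_max`.
#'
#' All z-scores produced under a panel are *direction aligned*: markers for
#' which lower raw values are worse (memory score, brain volumes) are negated
#' before referencing against controls, so that higher z always means more
#' abnormal.
#'
#' @param name character vector of marker names.
#' @param column name of the cohort column holding the raw value for each
#'   marker. The composite Trail Making Test score uses the derived column
#'   `"tmt_comp"` (see [composite_tmt()]).
#' @param direction `"higher_is_worse"` or `"lower_is_worse"` per marker.
#' @param transform `"identity"` or `"log2"` per marker.
#' @param covariate optional covariate column per marker (`NA` for plain
#'   z-scoring); covariate-adjusted markers are normalised as W-scores from a
#'   control-only regression.
#' @param z_thresholds strictly increasing positive z thresholds shared by all
#'   markers (one progression event per marker per threshold).
#' @param z_max trajectory ceiling in z units; must exceed `max(z_thresholds)`.
#'
#' @return An object of class `marker_panel`.
#' @seealso [default_marker_panel()] for the six-marker panel used throughout.
#' @export
marker_panel <- function(name, column, direction, transform = "identity",
                         covariate = NA_character_,
                         z_thresholds = c(1, 2, 3), z_max = 5) {
  m <- length(name)
  stopifnot(m >= 1, length(column) == m)
  direction <- rep_len(direction, m)
  transform <- rep_len(transform, m)
  covariate <- rep_len(covariate, m)
  if (!all(direction %in% c("higher_is_worse", "lower_is_worse")))
    stop("direction must be 'higher_is_worse' or 'lower_is_worse'")
  if (!all(transform %in% c("identity", "log2")))
    stop("transform must be 'identity' or 'log2'")
  if (any(diff(z_thresholds) <= 0) || any(z_thresholds <= 0))
    stop("z_thresholds must be strictly increasing and positive")
  if (z_max <= max(z_thresholds))
    stop("z_max must exceed the largest z threshold")
  structure(
    list(markers = data.frame(name = name, column = column,
                              direction = direction, transform = transform,
                              covariate = covariate,
                              stringsAsFactors = FALSE),
         z_thresholds = as.numeric(z_thresholds),
         z_max = as.numeric(z_max)),
    class = "marker_panel")
}

#' Default six-marker panel
#'
#' Logical memory and composite TMT (cognition), CSF p-tau181 (tau pathology),
#' white-matter hyperintensity volume (cerebrovascular, log2-transformed),
#' and whole-brain and hippocampal volumes (neurodegeneration). WMH and the
#' two volumes are covariate-corrected for total intracranial volume; memory
#' and the volumes are lower-is-worse and therefore inverted before z-scoring.
#' Events are placed at z = 1, 2, 3 with a trajectory ceiling of 5.
#'
#' @return A [marker_panel()] with six markers and 18 events.
#' @export
default_marker_panel <- function() {
  marker_panel(
    name      = c("lm",          "tmt",            "ptau",
                  "wmh",         "wbv",            "hip"),
    column    = c("lm_score",    "tmt_comp",       "csf_ptau181",
                  "wmh_ml",      "wbv_ml",         "hip_ml"),
    direction = c("lower_is_worse", "higher_is_worse", "higher_is_worse",
                  "higher_is_worse", "lower_is_worse", "lower_is_worse"),
    transform = c("identity", "identity", "identity",
                  "log2",     "identity", "identity"),
    covariate = c(NA, NA, NA, "tiv_ml", "tiv_ml", "tiv_ml"))
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", nrow(x$markers), " markers x ",
      length(x$z_thresholds), " z thresholds (",
      n_events(x), " events), z_max = ", x$z_max, "\n", sep = "")
  print(x$markers, row.names = FALSE)
  invisible(x)
}

n_markers <- function(panel) nrow(panel$markers)

#' Number of progression events implied by a panel
#'
#' @param panel a [marker_panel()].
#' @return markers times thresholds, the length of every event sequence.
#' @export
n_events <- function(panel) nrow(panel$markers) * length(panel$z_thresholds)
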
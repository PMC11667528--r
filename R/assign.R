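#' Subtype and stage individual subjects
#'
#' The subtype posterior is proportional to the mixture fraction times the
#' stage-marginal subject likelihood; the stage posterior is computed within
#' the maximum-likelihood subtype under the uniform stage prior. Ties break
#' to the lowest index. A subject whose maximum-likelihood stage is 0 is
#' indistinguishable from the control reference on every modelled marker and
#' is flagged `unsubtyped` with no subtype label.
#'
#' @param Z z-score matrix.
#' @param model a [fit_sustain()] result.
#' @return An object of class `sustain_assignment`: a data frame with columns
#'   `subject_id`, `ml_subtype` (NA when unsubtyped), `ml_stage`,
#'   `unsubtyped`, plus attributes `subtype_posterior` (n x C) and
#'   `stage_posterior` (n x (N+1), stages 0..N).
#' @export
assign_subjects <- function(Z, model) {
  stopifnot(inherits(model, "sustain_model"))
  panel <- model$panel
  n <- nrow(Z)
  C <- length(model$sequences)
  L <- subtype_loglik_matrix(Z, model$sequences, panel, model$noise_sd)
  post_subtype <- .responsibilities(L, model$fractions)
  ml_subtype <- max.col(post_subtype, ties.method = "first")

  N <- model$n_stages
  post_stage <- matrix(NA_real_, n, N + 1L)
  Es <- lapply(model$sequences, trajectory_matrix, panel = panel)
  for (c_idx in seq_len(C)) {
    rows <- which(ml_subtype == c_idx)
    if (!length(rows)) next
    SL <- stage_loglik_matrix(Z[rows, , drop = FALSE], Es[[c_idx]], model$noise_sd)
    post_stage[rows, ] <- exp(SL - .row_logsumexp(SL))
  }
  ml_stage <- max.col(post_stage, ties.method = "first") - 1L
  unsubtyped <- ml_stage == 0L
  df <- data.frame(subject_id = rownames(Z) %||% as.character(seq_len(n)),
                   ml_subtype = ifelse(unsubtyped, NA_integer_, ml_subtype),
                   ml_stage = ml_stage, unsubtyped = unsubtyped,
                   stringsAsFactors = FALSE)
  structure(df, subtype_posterior = post_subtype, stage_posterior = post_stage,
            class = c("sustain_assignment", "data.frame"))
}

#' Positional variance diagrams
#'
#' For each subtype, the matrix of MCMC frequencies with which each event
#' occupies each sequence position; spread across positions visualises
#' ordering uncertainty. When assignments are supplied, `dash_start` marks
#' the first stage from which the subtype's assigned-stage histogram shows
#' two consecutive stages with two subjects or fewer — positions beyond it
#' rest on very few individuals and are conventionally drawn dashed.
#'
#' @param model a [fit_sustain()] result with retained MCMC samples.
#' @param assignments optional [assign_subjects()] result for the dash rule.
#' @return list (one element per subtype) of class `sustain_pvd`, each with
#'   `P` (events x positions frequency matrix, rows summing to 1, rows
#'   labelled `marker:z`) and `dash_start` (NA when the rule never fires or
#'   assignments are absent).
#' @export
positional_variance <- function(model, assignments = NULL) {
  stopifnot(inherits(model, "sustain_model"))
  samples <- model$mcmc$samples
  if (!length(samples)) stop("model carries no retained MCMC samples")
  panel <- model$panel
  N <- model$n_stages
  R <- length(panel$z_thresholds)
  C <- length(model$sequences)
  ev_labels <- paste0(panel$markers$name[event_marker(seq_len(N), R)], ":",
                      panel$z_thresholds[event_thresh(seq_len(N), R)])
  out <- vector("list", C)
  for (c_idx in seq_len(C)) {
    P <- matrix(0, N, N, dimnames = list(ev_labels, seq_len(N)))
    for (s in samples) {
      seq_c <- s$sequences[[c_idx]]
      P[cbind(seq_c, seq_len(N))] <- P[cbind(seq_c, seq_len(N))] + 1
    }
    P <- P / length(samples)
    dash <- NA_integer_
    if (!is.null(assignments)) {
      stages <- assignments$ml_stage[!is.na(assignments$ml_subtype) &
                                       assignments$ml_subtype == c_idx]
      counts <- tabulate(stages, nbins = N)  # stages 1..N
      low <- which(counts[-N] <= 2 & counts[-1] <= 2)
      if (length(low)) dash <- low[1]
    }
    out[[c_idx]] <- structure(list(P = P, dash_start = dash, subtype = c_idx),
                              class = "sustain_pvd")
  }
  out
}

#' @export
print.sustain_pvd <- function(x, ...) {
  cat("<sustain_pvd> subtype ", x$subtype, ", ", nrow(x$P), " events",
      if (!is.na(x$dash_start)) paste0(", dashed from stage ", x$dash_start),
      "\n", sep = "")
  invisible(x)
}
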
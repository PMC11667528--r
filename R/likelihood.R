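#' @name sustain-likelihood
#' @title Likelihood of z-score data under an event sequence
#'
#' @description Given a subject's z vector and a sequence, the probability of
#' the data at stage k is a product of independent Gaussians centred on the
#' expected trajectory at k. The subject-level likelihood marginalises the
#' stage under a uniform prior over stages 0..N, and the cohort-level mixture
#' likelihood sums over subtypes weighted by their mixture fractions. All
#' internal computation is in log space.
NULL

.log2pi <- log(2 * pi)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# rows of log-sum-exp for a matrix
.row_logsumexp <- function(X) {
  m <- apply(X, 1, max)
  m + log(rowSums(exp(X - m)))
}

# n x (N+1) matrix of per-stage log-likelihoods for all subjects
stage_loglik_matrix <- function(Z, E, noise_sd) {
  W <- sweep(Z, 2, noise_sd, "/")            # subjects x markers
  F <- E / noise_sd                          # markers x stages
  D <- outer(rowSums(W^2), rep(1, ncol(E))) - 2 * (W %*% F) +
    rep(colSums(F^2), each = nrow(Z))
  -0.5 * D - 0.5 * ncol(Z) * .log2pi - sum(log(noise_sd))
}

#' Per-stage likelihood of a z vector
#'
#' Product over markers of normal densities centred on the expected
#' trajectory at the given stage, with per-marker noise SD.
#'
#' @param z numeric z vector (one subject, panel order).
#' @param sequence valid event-id vector.
#' @param panel a [marker_panel()].
#' @param stage integer stage in `[0, N]`.
#' @param noise_sd per-marker noise SDs (default 1: data are control-scaled).
#' @param log return the log density?
#' @return scalar (log-)density.
#' @export
stage_likelihood <- function(z, sequence, panel, stage,
                             noise_sd = rep(1, length(z)), log = FALSE) {
  E <- trajectory_matrix(sequence, panel)
  ll <- sum(stats::dnorm(z, mean = E[, stage + 1L], sd = noise_sd, log = TRUE))
  if (log) ll else exp(ll)
}

#' Stage-marginal likelihood of a z vector
#'
#' Average of [stage_likelihood()] over all stages 0..N (uniform stage
#' prior), computed stably in log space.
#'
#' @inheritParams stage_likelihood
#' @return scalar (log-)likelihood.
#' @export
subject_likelihood <- function(z, sequence, panel,
                               noise_sd = rep(1, length(z)), log = FALSE) {
  E <- trajectory_matrix(sequence, panel)
  ll <- stage_loglik_matrix(matrix(z, 1), E, noise_sd)
  out <- logsumexp(ll[1, ]) - log(ncol(E))
  if (log) out else exp(out)
}

# n-vector of stage-marginal log-likelihoods for all subjects under one sequence
subject_loglik_vector <- function(Z, sequence, panel, noise_sd) {
  E <- trajectory_matrix(sequence, panel)
  .row_logsumexp(stage_loglik_matrix(Z, E, noise_sd)) - log(ncol(E))
}

# n x C matrix of per-subtype stage-marginal log-likelihoods
subtype_loglik_matrix <- function(Z, sequences, panel, noise_sd) {
  vapply(sequences, function(s) subject_loglik_vector(Z, s, panel, noise_sd),
         numeric(nrow(Z)))
}

#' Mixture log-likelihood of a cohort under a subtype model
#'
#' Sum over subjects of the log of the fraction-weighted sum over subtypes of
#' the stage-marginal subject likelihood.
#'
#' @param Z z-score matrix (subjects x markers).
#' @param model a `sustain_model` (see [fit_sustain()]), or a list with
#'   elements `sequences`, `fractions` and optionally `noise_sd`.
#' @param panel a [marker_panel()].
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(Z, model, panel) {
  noise_sd <- model$noise_sd %||% rep(1, ncol(Z))
  f <- model$fractions
  if (abs(sum(f) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  L <- subtype_loglik_matrix(Z, model$sequences, panel, noise_sd)
  sum(.row_logsumexp(sweep(L, 2, log(f), "+")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
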
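#' Fit settings for the subtype-and-stage model
#'
#' @param n_startpoints random greedy restarts for the single-subtype fit.
#' @param n_mcmc Metropolis-Hastings iterations for the uncertainty pass.
#' @param burn_in iterations discarded before retaining samples.
#' @param thinning keep every `thinning`-th post-burn-in sample.
#' @param seed integer seed controlling every random draw of the fit.
#' @param max_subtypes largest number of subtypes considered in
#'   cross-validation.
#' @param cv_folds number of cross-validation folds.
#' @param cvic_parsimony_margin a more complex model must beat a simpler one
#'   by at least this much CVIC to be selected (default 6).
#' @param n_bisections random bisections tried per subtype when splitting.
#' @param max_alternations cap on sequence/fraction alternation rounds.
#' @return list of class `sustain_settings`.
#' @export
sustain_settings <- function(n_startpoints = 25L, n_mcmc = 100000L,
                             burn_in = 10000L, thinning = 10L, seed = 1L,
                             max_subtypes = 4L, cv_folds = 10L,
                             cvic_parsimony_margin = 6,
                             n_bisections = 5L, max_alternations = 100L) {
  s <- list(n_startpoints = as.integer(n_startpoints),
            n_mcmc = as.integer(n_mcmc), burn_in = as.integer(burn_in),
            thinning = as.integer(thinning), seed = as.integer(seed),
            max_subtypes = as.integer(max_subtypes),
            cv_folds = as.integer(cv_folds),
            cvic_parsimony_margin = cvic_parsimony_margin,
            n_bisections = as.integer(n_bisections),
            max_alternations = as.integer(max_alternations))
  stopifnot(s$n_startpoints > 0, s$n_mcmc > 0, s$burn_in >= 0,
            s$burn_in < s$n_mcmc, s$thinning > 0, s$max_subtypes > 0,
            s$cv_folds > 1, s$n_bisections > 0, s$max_alternations > 0)
  class(s) <- "sustain_settings"
  s
}

# deterministic per-stage substreams derived from the root seed, so one
# stage's draws do not perturb another's
.substream <- function(seed, label) {
  offsets <- c(startpoints = 11L, split = 23L, mcmc = 37L, folds = 53L,
               generator = 71L, fisher = 89L)
  (as.integer(seed) * 97L + offsets[[label]]) %% .Machine$integer.max
}

# valid insertion range for event e once removed from a sequence:
# strictly after its previous-threshold event, no later than its
# next-threshold event (positions refer to the reduced sequence)
.insert_range <- function(reduced, e, n_thresh) {
  r <- event_thresh(e, n_thresh)
  lo <- 1L
  hi <- length(reduced) + 1L
  if (r > 1L) lo <- match(e - 1L, reduced) + 1L
  if (r < n_thresh) hi <- match(e + 1L, reduced)
  lo:hi
}

.insert_at <- function(reduced, e, p) append(reduced, e, after = p - 1L)

#' Greedy coordinate ascent over event orderings
#'
#' Repeatedly takes each event in turn, tries every constraint-respecting
#' position for it, and keeps the placement maximising the (optionally
#' subject-weighted) data log-likelihood, until a full pass makes no
#' improvement. The returned ordering's likelihood is never below the initial
#' one; ties go to the earliest position.
#'
#' @param Z z-score matrix (subjects x markers).
#' @param panel a [marker_panel()].
#' @param initial valid starting sequence.
#' @param noise_sd per-marker noise SDs.
#' @param weights optional per-subject weights (responsibilities).
#' @return list with `sequence` and its weighted log-likelihood `loglik`.
#' @export
greedy_optimize_sequence <- function(Z, panel, initial,
                                     noise_sd = rep(1, ncol(Z)),
                                     weights = NULL) {
  if (!validate_event_sequence(initial, panel)) stop("invalid initial sequence")
  if (is.null(weights)) weights <- rep(1, nrow(Z))
  R <- length(panel$z_thresholds)
  score <- function(s) sum(weights * subject_loglik_vector(Z, s, panel, noise_sd))
  s <- initial
  best <- score(s)
  repeat {
    improved <- FALSE
    for (e in seq_len(n_events(panel))) {
      reduced <- s[s != e]
      slots <- .insert_range(reduced, e, R)
      if (length(slots) == 1L) next
      cand_scores <- vapply(slots, function(p) score(.insert_at(reduced, e, p)),
                            numeric(1))
      k <- which.max(cand_scores)
      if (cand_scores[k] > best + 1e-12) {
        s <- .insert_at(reduced, e, slots[k])
        best <- cand_scores[k]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(sequence = s, loglik = best)
}

#' Metropolis-Hastings sampling over constrained event orderings
#'
#' The proposal removes a uniformly chosen event from a uniformly chosen
#' subtype's sequence and reinserts it at a uniformly chosen
#' constraint-respecting position; since the set of legal positions is
#' determined by the reduced sequence, the proposal is symmetric and the
#' acceptance probability is `min(1, exp(delta log-likelihood))`. Mixture
#' fractions are held at their maximum-likelihood values during sampling.
#'
#' @param Z z-score matrix.
#' @param panel a [marker_panel()].
#' @param sequences list of starting sequences (one per subtype).
#' @param fractions mixture fractions summing to 1.
#' @param settings a [sustain_settings()]; `n_mcmc`, `burn_in`, `thinning`
#'   and `seed` are used.
#' @param noise_sd per-marker noise SDs.
#' @return list of class `sustain_mcmc`: `samples` (list with `sequences`,
#'   `fractions`, `loglik` per retained draw), `acceptance_rate`,
#'   `loglik_trace` (full chain), and the maximum-likelihood state visited.
#' @export
mcmc_sample <- function(Z, panel, sequences, fractions, settings,
                        noise_sd = rep(1, ncol(Z))) {
  stopifnot(inherits(settings, "sustain_settings"))
  for (s in sequences) if (!validate_event_sequence(s, panel))
    stop("invalid starting sequence")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(.substream(settings$seed, "mcmc"))
  C <- length(sequences)
  R <- length(panel$z_thresholds)
  logf <- log(fractions)

  L <- subtype_loglik_matrix(Z, sequences, panel, noise_sd)
  total <- sum(.row_logsumexp(sweep(L, 2, logf, "+")))

  n_keep <- (settings$n_mcmc - settings$burn_in) %/% settings$thinning
  samples <- vector("list", n_keep)
  kept <- 0L
  accepted <- 0L
  trace <- numeric(settings$n_mcmc)
  best <- list(sequences = sequences, fractions = fractions, loglik = total)

  for (it in seq_len(settings$n_mcmc)) {
    c_idx <- if (C == 1L) 1L else sample.int(C, 1L)
    e <- sample.int(n_events(panel), 1L)
    cur <- sequences[[c_idx]]
    reduced <- cur[cur != e]
    slots <- .insert_range(reduced, e, R)
    p <- slots[sample.int(length(slots), 1L)]
    prop <- .insert_at(reduced, e, p)
    l_prop <- subject_loglik_vector(Z, prop, panel, noise_sd)
    L_prop <- L
    L_prop[, c_idx] <- l_prop
    total_prop <- sum(.row_logsumexp(sweep(L_prop, 2, logf, "+")))
    if (log(stats::runif(1)) < total_prop - total) {
      sequences[[c_idx]] <- prop
      L <- L_prop
      total <- total_prop
      accepted <- accepted + 1L
      if (total > best$loglik)
        best <- list(sequences = sequences, fractions = fractions, loglik = total)
    }
    trace[it] <- total
    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thinning == 0L) {
      kept <- kept + 1L
      samples[[kept]] <- list(sequences = sequences, fractions = fractions,
                              loglik = total)
    }
  }
  structure(list(samples = samples[seq_len(kept)],
                 acceptance_rate = accepted / settings$n_mcmc,
                 loglik_trace = trace, best = best),
            class = "sustain_mcmc")
}

# E-step responsibilities; returns n x C matrix
.responsibilities <- function(L, fractions) {
  A <- sweep(L, 2, log(fractions), "+")
  r <- exp(A - .row_logsumexp(A))
  r / rowSums(r)
}

# one maximum-likelihood fit at a fixed number of subtypes, splitting from a
# parent model when C > 1
.fit_ml <- function(Z, panel, n_subtypes, settings, noise_sd) {
  n <- nrow(Z)
  floor_f <- 1 / (10 * n)

  alternate <- function(sequences, fractions,
                        max_iter = settings$max_alternations) {
    C <- length(sequences)
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      L <- subtype_loglik_matrix(Z, sequences, panel, noise_sd)
      r <- .responsibilities(L, fractions)
      # re-seed a collapsed subtype from the worst-fit subjects
      hard <- tabulate(max.col(r, ties.method = "first"), C)
      if (any(hard == 0L)) {
        marg <- .row_logsumexp(sweep(L, 2, log(fractions), "+"))
        worst <- order(marg)[seq_len(max(2L, n %/% 10L))]
        for (c_empty in which(hard == 0L)) {
          sequences[[c_empty]] <- greedy_optimize_sequence(
            Z[worst, , drop = FALSE], panel, random_event_sequence(panel),
            noise_sd)$sequence
        }
        L <- subtype_loglik_matrix(Z, sequences, panel, noise_sd)
        r <- .responsibilities(L, fractions)
      }
      fractions <- pmax(colMeans(r), floor_f)
      fractions <- fractions / sum(fractions)
      for (c_idx in seq_len(C)) {
        sequences[[c_idx]] <- greedy_optimize_sequence(
          Z, panel, sequences[[c_idx]], noise_sd, weights = r[, c_idx])$sequence
      }
      L <- subtype_loglik_matrix(Z, sequences, panel, noise_sd)
      ll <- sum(.row_logsumexp(sweep(L, 2, log(fractions), "+")))
      if (ll - ll_old < 1e-6) break
      ll_old <- ll
    }
    list(sequences = sequences, fractions = fractions, loglik = ll)
  }

  if (n_subtypes == 1L) {
    set.seed(.substream(settings$seed, "startpoints"))
    best <- NULL
    for (k in seq_len(settings$n_startpoints)) {
      fit <- greedy_optimize_sequence(Z, panel, random_event_sequence(panel),
                                      noise_sd)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    return(list(sequences = list(best$sequence), fractions = 1,
                loglik = best$loglik))
  }

  parent <- .fit_ml(Z, panel, n_subtypes - 1L, settings, noise_sd)
  Lp <- subtype_loglik_matrix(Z, parent$sequences, panel, noise_sd)
  rp <- .responsibilities(Lp, parent$fractions)
  member <- max.col(rp, ties.method = "first")

  set.seed(.substream(settings$seed, "split") + n_subtypes)
  best <- NULL
  for (c_split in seq_along(parent$sequences)) {
    idx <- which(member == c_split)
    if (length(idx) < 4L) next
    for (b in seq_len(settings$n_bisections)) {
      half <- sample(idx, length(idx) %/% 2L)
      other <- setdiff(idx, half)
      s1 <- greedy_optimize_sequence(Z[half, , drop = FALSE], panel,
                                     random_event_sequence(panel), noise_sd)$sequence
      s2 <- greedy_optimize_sequence(Z[other, , drop = FALSE], panel,
                                     random_event_sequence(panel), noise_sd)$sequence
      seqs <- parent$sequences
      seqs[[c_split]] <- s1
      seqs <- c(seqs, list(s2))
      frac <- parent$fractions
      frac_split <- frac[c_split]
      frac[c_split] <- frac_split * length(half) / length(idx)
      frac <- c(frac, frac_split * length(other) / length(idx))
      # short alternation to rank candidate splits; the winner is polished below
      cand <- alternate(seqs, frac / sum(frac),
                        max_iter = min(5L, settings$max_alternations))
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
  }
  if (is.null(best)) stop("no subtype large enough to split at C = ", n_subtypes)
  alternate(best$sequences, best$fractions)
}

#' Fit the z-score subtype-and-stage model
#'
#' Hierarchical maximum-likelihood fit: the single-subtype ordering is found
#' by multi-start greedy ascent; each further subtype is introduced by
#' randomised bisection of an existing subtype's maximum-likelihood members,
#' refined by alternating responsibility-weighted sequence re-optimisation
#' with mixture-fraction updates until the log-likelihood stabilises. A final
#' Metropolis-Hastings pass quantifies ordering uncertainty; the reported
#' sequences are the highest-likelihood state visited.
#'
#' @param Z z-score matrix from [build_zscore_matrix()].
#' @param panel a [marker_panel()].
#' @param n_subtypes number of subtypes C (>= 1).
#' @param settings a [sustain_settings()].
#' @param noise_sd per-marker noise SDs; default 1 because markers are
#'   z-scored against controls.
#' @return An object of class `sustain_model`: `sequences`, `fractions`,
#'   `noise_sd`, `n_stages`, `loglik`, `mcmc` (a `sustain_mcmc`), `settings`,
#'   `panel`.
#' @export
fit_sustain <- function(Z, panel, n_subtypes, settings = sustain_settings(),
                        noise_sd = rep(1, ncol(Z))) {
  stopifnot(inherits(panel, "marker_panel"), n_subtypes >= 1)
  if (nrow(Z) == 0) stop("empty z-score matrix")
  if (n_subtypes > nrow(Z)) stop("more subtypes than subjects")
  ml <- .fit_ml(Z, panel, as.integer(n_subtypes), settings, noise_sd)
  mc <- mcmc_sample(Z, panel, ml$sequences, ml$fractions, settings, noise_sd)
  final <- if (mc$best$loglik > ml$loglik) mc$best else ml
  structure(list(sequences = final$sequences, fractions = final$fractions,
                 noise_sd = noise_sd, n_stages = n_events(panel),
                 loglik = final$loglik, mcmc = mc, settings = settings,
                 panel = panel),
            class = "sustain_model")
}

#' @export
print.sustain_model <- function(x, ...) {
  C <- length(x$sequences)
  cat("<sustain_model> ", C, " subtype(s), ", x$n_stages, " stages, loglik ",
      format(x$loglik), "\n", sep = "")
  R <- length(x$panel$z_thresholds)
  for (c_idx in seq_len(C)) {
    s <- x$sequences[[c_idx]]
    lab <- paste0(x$panel$markers$name[event_marker(s, R)], ":",
                  x$panel$z_thresholds[event_thresh(s, R)])
    cat(sprintf("  subtype %d (fraction %.3f): %s\n", c_idx,
                x$fractions[c_idx], paste(lab, collapse = " > ")))
  }
  invisible(x)
}
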
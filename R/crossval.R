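#' Cross-validated model selection by CVIC
#'
#' Subjects are partitioned into seeded folds; for each fold and each number
#' of subtypes C the model is fitted on the training subjects and the
#' held-out subjects' predictive log-likelihood is computed by averaging the
#' mixture likelihood over the retained MCMC samples (so ordering uncertainty
#' contributes to the criterion, not just the point estimate). The
#' cross-validation information criterion is
#' `CVIC(C) = -2 * sum of out-of-fold predictive log-likelihoods`; lower is
#' better. A parsimony margin guards against over-selection: the chosen C is
#' the smallest whose CVIC no more complex model improves upon by at least
#' `cvic_parsimony_margin`.
#'
#' @param Z z-score matrix.
#' @param panel a [marker_panel()].
#' @param max_subtypes largest C to evaluate.
#' @param settings a [sustain_settings()]; `cv_folds`, MCMC sizes and `seed`
#'   are used.
#' @param noise_sd per-marker noise SDs.
#' @return An object of class `sustain_cvic`: data frame `cvic`
#'   (`n_subtypes`, `cvic`), `selected` C, and the per-fold log-likelihood
#'   matrix `fold_loglik`.
#' @export
cross_validate_cvic <- function(Z, panel, max_subtypes = 4L,
                                settings = sustain_settings(),
                                noise_sd = rep(1, ncol(Z))) {
  n <- nrow(Z)
  K <- settings$cv_folds
  if (n < K) stop("fewer subjects than folds")
  set.seed(.substream(settings$seed, "folds"))
  fold <- sample(rep_len(seq_len(K), n))
  if (min(tabulate(fold, K)) < 2) stop("a fold has fewer than 2 subjects")

  fold_ll <- matrix(NA_real_, K, max_subtypes,
                    dimnames = list(paste0("fold", seq_len(K)),
                                    paste0("C", seq_len(max_subtypes))))
  for (k in seq_len(K)) {
    train <- Z[fold != k, , drop = FALSE]
    test <- Z[fold == k, , drop = FALSE]
    fold_settings <- settings
    fold_settings$seed <- as.integer((settings$seed * 131L + k) %% .Machine$integer.max)
    for (C in seq_len(max_subtypes)) {
      model <- fit_sustain(train, panel, C, fold_settings, noise_sd)
      fold_ll[k, C] <- sum(.predictive_loglik(test, model))
    }
  }
  cvic <- -2 * colSums(fold_ll)
  selected <- .select_cvic(cvic, settings$cvic_parsimony_margin)
  structure(list(cvic = data.frame(n_subtypes = seq_len(max_subtypes),
                                   cvic = unname(cvic)),
                 selected = selected, fold_loglik = fold_ll,
                 fold = fold),
            class = "sustain_cvic")
}

# per-subject log predictive likelihood, averaged over retained MCMC samples;
# duplicate chain states are collapsed and weighted by their multiplicity
.predictive_loglik <- function(Z, model) {
  samples <- model$mcmc$samples
  if (!length(samples)) samples <- list(list(sequences = model$sequences,
                                             fractions = model$fractions))
  panel <- model$panel
  keys <- vapply(samples, function(s)
    paste(unlist(s$sequences), collapse = ","), "")
  first <- !duplicated(keys)
  counts <- as.numeric(table(keys)[keys[first]])
  uniq <- samples[first]
  per_sample <- vapply(seq_along(uniq), function(j) {
    s <- uniq[[j]]
    L <- subtype_loglik_matrix(Z, s$sequences, panel, model$noise_sd)
    .row_logsumexp(sweep(L, 2, log(s$fractions), "+")) + log(counts[j])
  }, numeric(nrow(Z)))
  if (nrow(Z) == 1L) per_sample <- matrix(per_sample, 1)
  .row_logsumexp(per_sample) - log(length(samples))
}

# smallest C that no more complex model beats by >= margin
.select_cvic <- function(cvic, margin) {
  for (C in seq_along(cvic)) {
    if (C == length(cvic) || all(cvic[C] - cvic[(C + 1):length(cvic)] < margin))
      return(C)
  }
  length(cvic)
}

#' @export
print.sustain_cvic <- function(x, ...) {
  cat("<sustain_cvic> selected", x$selected, "subtype(s)\n")
  print(x$cvic, row.names = FALSE)
  invisible(x)
}
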
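# shared in-code fixtures; everything is generated, nothing read from disk

# minimal complete subject row with overridable fields
make_subject_row <- function(id, ...) {
  row <- list(subject_id = id, baseline_diagnosis = "CN", age_years = 72,
              sex = "female", apoe_e4_carrier = FALSE, education_years = 16,
              csf_abeta = 300, csf_ptau181 = 19, wmh_ml = 2.5, wbv_ml = 1090,
              hip_ml = 5.6, tiv_ml = 1433, lm_score = 14, tmt_a_s = 31,
              tmt_b_s = 80, hypertension = FALSE, stroke = FALSE,
              lacune_present = FALSE, cmb_present = FALSE, followup = "")
  mods <- list(...)
  row[names(mods)] <- mods
  as.data.frame(row, stringsAsFactors = FALSE)
}

make_subject_df <- function(n = 3, ids = sprintf("s%02d", seq_len(n)), ...) {
  do.call(rbind, lapply(ids, function(id) make_subject_row(id, ...)))
}

write_cohort_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# enumerate all valid sequences for a small panel (used as oracle)
enumerate_sequences <- function(panel) {
  N <- n_events(panel)
  R <- length(panel$z_thresholds)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  Filter(function(s) validate_event_sequence(s, panel), perms(seq_len(N)))
}

# brute-force per-subject marginal log-likelihood, used as an enumeration
# oracle (direct stage summation with scalar normal densities)
subject_loglik_vector_test <- function(Z, s, panel, noise_sd = rep(1, ncol(Z))) {
  N <- n_events(panel)
  M <- ncol(Z)
  sapply(seq_len(nrow(Z)), function(i) {
    log(mean(sapply(0:N, function(k) {
      mu <- sapply(seq_len(M), function(m) expected_trajectory(s, panel, m, k))
      prod(dnorm(Z[i, ], mu, noise_sd))
    })))
  })
}

# settings small enough for unit tests
quick_settings <- function(seed = 1L, ...) {
  sustain_settings(n_startpoints = 3L, n_mcmc = 600L, burn_in = 100L,
                   thinning = 5L, seed = seed, n_bisections = 2L,
                   max_alternations = 8L, ...)
}
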
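#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the package is validated under: 86
#' amyloid-negative controls and 376 amyloid-positive cases, three planted
#' subtypes in proportions 145/88/100 of the subtyped mass with an 11%
#' (43/376) stage-0 subpopulation, unit-variance Gaussian noise on the z
#' scale, a bimodal CSF amyloid mixture, a log-normal WMH distribution, a
#' linear TIV effect on the volumetric markers, and control marker
#' means/SDs anchored to the reference-control column of the cohort table.
#'
#' @param seed integer root seed.
#' @param n_controls,n_cases group sizes.
#' @param panel a [marker_panel()].
#' @param planted_sequences list of valid event sequences, one per subtype
#'   (defaults: memory-led, WMH-led and p-tau-led orderings).
#' @param fractions subtype mixing proportions (sum 1).
#' @param stage0_mass probability that a case carries no events (stage 0).
#' @param stage_distribution `"uniform"` over stages 1..N for subtyped cases.
#' @param noise_sd_z z-scale noise SD added to the planted trajectory.
#' @param amyloid_components 2-column setup of the CSF amyloid mixture:
#'   list of `c(mean, sd, weight)` for the abnormal and normal component.
#' @param amyloid_margin buffer (pg/mL) kept between generated values and the
#'   implied cut-point so group membership is unambiguous.
#' @param control_models per-marker generative parameters on the transformed,
#'   direction-aligned scale (plain: `mean`, `sd`; TIV-adjusted:
#'   `intercept`, `slope`, `resid_sd`).
#' @param tiv_mean,tiv_sd total intracranial volume distribution (mL).
#' @param tmt_a_mean,tmt_a_sd TMT part A distribution (s).
#' @param group_shifts per-group demographic structure (age offsets,
#'   hypertension/sex/lacune/microbleed probabilities; groups ordered
#'   unsubtyped, then subtypes).
#' @param progression_rates probability of diagnostic progression within 24
#'   months per stage band (early/middle/late thirds).
#' @param missing_followup_rate probability a case has no visit inside the
#'   24-month horizon.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_controls = 86L,
    n_cases = 376L,
    panel = default_marker_panel(),
    planted_sequences = .default_planted_sequences(),
    fractions = c(145, 88, 100) / 333,
    stage0_mass = 43 / 376,
    stage_distribution = "uniform",
    noise_sd_z = 1,
    amyloid_components = list(c(mean = 190, sd = 40, weight = 0.55),
                              c(mean = 343, sd = 50, weight = 0.45)),
    amyloid_margin = 10,
    control_models = .default_control_models(),
    tiv_mean = 1433, tiv_sd = 137,
    tmt_a_mean = 31.4, tmt_a_sd = 10,
    group_shifts = .default_group_shifts(length(planted_sequences)),
    progression_rates = c(early = 0.10, middle = 0.25, late = 0.40),
    missing_followup_rate = 0.15) {
  cfg <- list(seed = as.integer(seed), n_controls = as.integer(n_controls),
              n_cases = as.integer(n_cases), panel = panel,
              planted_sequences = planted_sequences,
              fractions = fractions, stage0_mass = stage0_mass,
              stage_distribution = match.arg(stage_distribution, "uniform"),
              noise_sd_z = noise_sd_z,
              amyloid_components = amyloid_components,
              amyloid_margin = amyloid_margin,
              control_models = control_models,
              tiv_mean = tiv_mean, tiv_sd = tiv_sd,
              tmt_a_mean = tmt_a_mean, tmt_a_sd = tmt_a_sd,
              group_shifts = group_shifts,
              progression_rates = progression_rates,
              missing_followup_rate = missing_followup_rate)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (stage0_mass < 0 || stage0_mass >= 1) stop("stage0_mass must lie in [0, 1)")
  if (length(planted_sequences) != length(fractions))
    stop("one fraction per planted sequence")
  for (s in planted_sequences) if (!validate_event_sequence(s, panel))
    stop("invalid planted sequence")
  if (amyloid_components[[1]]["mean"] >= amyloid_components[[2]]["mean"])
    stop("amyloid components must be ordered by mean")
  if (noise_sd_z < 0) stop("noise_sd_z must be non-negative")
  class(cfg) <- "synthetic_config"
  cfg
}

# hand-specified orderings qualitatively matching the three observed
# subtypes: memory-led (LM first, then p-tau, hippocampus, whole brain),
# WMH-led (WMH first, then LM, whole brain, TMT) and p-tau-led (p-tau first,
# then LM, hippocampus, TMT); marker ids lm=1 tmt=2 ptau=3 wmh=4 wbv=5 hip=6,
# event id = (marker-1)*3 + threshold
.default_planted_sequences <- function() {
  list(
    memory_led = c(1L, 2L, 3L, 7L, 16L, 8L, 17L, 13L, 9L, 18L, 14L, 4L,
                   15L, 5L, 10L, 6L, 11L, 12L),
    wmh_led    = c(10L, 11L, 12L, 1L, 13L, 2L, 14L, 4L, 3L, 15L, 5L, 6L,
                   7L, 16L, 8L, 17L, 9L, 18L),
    ptau_led   = c(7L, 8L, 9L, 1L, 16L, 2L, 17L, 4L, 3L, 18L, 5L, 10L,
                   6L, 11L, 13L, 12L, 14L, 15L))
}

# generative control models on the transformed, direction-aligned scale,
# anchored to the reference-control marker means/SDs of the cohort table
.default_control_models <- function() {
  list(
    lm   = list(type = "plain", mean = -14.6, sd = 2.6),
    tmt  = list(type = "plain", mean = 47.8, sd = 43.6),
    ptau = list(type = "plain", mean = 18.8, sd = 7.4),
    # log2 WMH ~ TIV; intercept chosen so the control median is ~2.5 mL
    wmh  = list(type = "adjusted", intercept = 0.6035, slope = 0.0005,
                resid_sd = 0.8),
    # aligned whole-brain = -wbv; raw wbv ~ 303.2 + 0.55 * TIV
    wbv  = list(type = "adjusted", intercept = -303.2, slope = -0.55,
                resid_sd = 65),
    # aligned hippocampus = -hip; raw hip ~ 3.45 + 0.0015 * TIV
    hip  = list(type = "adjusted", intercept = -3.45, slope = -0.0015,
                resid_sd = 0.6))
}

.default_group_shifts <- function(n_subtypes) {
  # groups ordered: unsubtyped (stage 0), then subtypes
  pick <- function(x, default) rep_len(c(x, default), n_subtypes + 1L)[seq_len(n_subtypes + 1L)]
  list(age_mean = pick(c(69.8, 73.8, 77.9, 71.4), 73),
       age_sd = rep(6.8, n_subtypes + 1L),
       male_prob = pick(c(0.49, 0.61, 0.55, 0.39), 0.5),
       education_mean = pick(c(17.1, 16.3, 15.8, 15.6), 16),
       education_sd = rep(2.6, n_subtypes + 1L),
       apoe_prob = pick(c(0.58, 0.70, 0.44, 0.72), 0.6),
       hypertension_prob = pick(c(0.42, 0.48, 0.65, 0.51), 0.5),
       lacune_prob = pick(c(0, 0, 0.05, 0.02), 0.02),
       cmb_prob = pick(c(0.12, 0.14, 0.23, 0.22), 0.18),
       stroke_prob = pick(c(0, 0, 0.01, 0.02), 0.01))
}

#' Study-shaped synthetic configuration
#'
#' The default study-shaped configuration: 86 controls, 376 cases, subtyped
#' fractions 145/88/100 of 333 with 43/376 stage-0 mass, the three
#' hand-specified memory-led / WMH-led / p-tau-led orderings, and control
#' marker anchors from the reference-control column of the cohort table.
#'
#' @param seed integer root seed.
#' @return a [synthetic_config()].
#' @export
make_paper_shaped_config <- function(seed = 1L) synthetic_config(seed = seed)

# standardise draws to exact sample mean/sd so the fitted control reference
# reproduces the generative parameters and the z round-trip is exact
.std <- function(n) {
  e <- stats::rnorm(n)
  (e - mean(e)) / stats::sd(e)
}

# residuals exactly orthogonal to the covariate with residual SD (n-2
# denominator) exactly `s`
.std_resid <- function(covariate, s) {
  e <- stats::resid(stats::lm(stats::rnorm(length(covariate)) ~ covariate))
  e * s / sqrt(sum(e^2) / (length(covariate) - 2))
}

.truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# invert the normalisation map: aligned value y -> raw marker columns
.raw_from_aligned <- function(df, panel, y_matrix) {
  for (i in seq_len(n_markers(panel))) {
    marker <- panel$markers[i, ]
    y <- y_matrix[, i]
    t_val <- if (marker$direction == "lower_is_worse") -y else y
    raw <- if (marker$transform == "log2") 2^t_val else t_val
    df[[marker$column]] <- raw
  }
  df
}

#' Generate a seeded synthetic cohort with planted ground truth
#'
#' Controls are drawn at z = 0 with unit control-scale noise and exactly
#' reproduce the generative reference when re-fitted (sample means/SDs and
#' control-only regressions are standardised to their nominal values), so
#' that at `noise_sd_z = 0` the z-score round-trip is exact. Cases draw a
#' subtype (or the stage-0 subpopulation), a stage, planted z =
#' expected trajectory + noise, and raw markers by inverting the
#' normalisation maps: direction flip, TIV regression plus residual for the
#' volumetric markers, `2^y` for WMH, and a TMT A/B pair consistent with the
#' planted composite (part B censored at the 300 s ceiling). CSF amyloid is
#' sampled from the bimodal mixture with cases below and controls above the
#' implied cut-point; diagnoses and follow-up are assigned by stage band.
#'
#' @param config a [synthetic_config()].
#' @return list with `controls` and `cases` ([cohort()]s) and `truth`
#'   (data frame: `subject_id`, `subtype` (NA for stage-0 cases), `stage`,
#'   planted pre-noise and noisy z columns `z_true_*` / `z_*`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.substream(config$seed, "generator"))
  panel <- config$panel
  M <- n_markers(panel)
  N <- n_events(panel)
  cut_implied <- stats::qnorm(0.99, config$amyloid_components[[1]]["mean"],
                              config$amyloid_components[[1]]["sd"])

  ## ---- controls -------------------------------------------------------
  nC <- config$n_controls
  tiv_c <- stats::rnorm(nC, config$tiv_mean, config$tiv_sd)
  Yc <- matrix(NA_real_, nC, M, dimnames = list(NULL, panel$markers$name))
  for (i in seq_len(M)) {
    cm <- config$control_models[[panel$markers$name[i]]]
    Yc[, i] <- if (cm$type == "plain") {
      cm$mean + cm$sd * .std(nC)
    } else {
      cm$intercept + cm$slope * tiv_c + .std_resid(tiv_c, cm$resid_sd)
    }
  }
  controls <- data.frame(subject_id = sprintf("ctrl%03d", seq_len(nC)),
                         baseline_diagnosis = "CN",
                         age_years = stats::rnorm(nC, 72.4, 5.2),
                         sex = ifelse(stats::runif(nC) < 0.58, "male", "female"),
                         apoe_e4_carrier = FALSE,
                         education_years = round(.truncated_normal(nC, 16.5, 2.5, 6, 20)),
                         csf_abeta = .truncated_normal(
                           nC, config$amyloid_components[[2]]["mean"],
                           config$amyloid_components[[2]]["sd"],
                           lower = cut_implied + config$amyloid_margin),
                         csf_ptau181 = NA_real_, wmh_ml = NA_real_,
                         wbv_ml = NA_real_, hip_ml = NA_real_,
                         tiv_ml = tiv_c, lm_score = NA_real_,
                         tmt_a_s = NA_real_, tmt_b_s = NA_real_,
                         hypertension = stats::runif(nC) < 0.35,
                         stroke = FALSE,
                         lacune_present = FALSE,
                         cmb_present = stats::runif(nC) < 0.14,
                         followup = I(replicate(nC, data.frame(
                           month = c(6L, 12L, 24L),
                           diagnosis = c("CN", "CN", "CN")), simplify = FALSE)),
                         stringsAsFactors = FALSE)
  controls <- .raw_from_aligned(controls, panel, Yc)
  controls <- .finalize_tmt(controls, Yc[, "tmt"], config)

  ## ---- cases ----------------------------------------------------------
  nX <- config$n_cases
  Csub <- length(config$planted_sequences)
  is0 <- stats::runif(nX) < config$stage0_mass
  subtype <- rep(NA_integer_, nX)
  subtype[!is0] <- sample.int(Csub, sum(!is0), replace = TRUE,
                              prob = config$fractions)
  stage <- integer(nX)
  stage[!is0] <- sample.int(N, sum(!is0), replace = TRUE)  # uniform on 1..N

  Etraj <- lapply(config$planted_sequences, trajectory_matrix, panel = panel)
  z_true <- matrix(0, nX, M, dimnames = list(NULL, panel$markers$name))
  for (j in which(!is0)) z_true[j, ] <- Etraj[[subtype[j]]][, stage[j] + 1L]
  z_noisy <- z_true + config$noise_sd_z * matrix(stats::rnorm(nX * M), nX, M)

  tiv_x <- stats::rnorm(nX, config$tiv_mean, config$tiv_sd)
  Yx <- matrix(NA_real_, nX, M, dimnames = list(NULL, panel$markers$name))
  for (i in seq_len(M)) {
    cm <- config$control_models[[panel$markers$name[i]]]
    Yx[, i] <- if (cm$type == "plain") {
      cm$mean + cm$sd * z_noisy[, i]
    } else {
      cm$intercept + cm$slope * tiv_x + cm$resid_sd * z_noisy[, i]
    }
  }

  grp <- ifelse(is0, 1L, subtype + 1L)  # index into group_shifts
  gs <- config$group_shifts
  band <- cut(stage, breaks = c(-1, 0, 6, 12, N), labels = FALSE)  # 1..4
  dx_prob <- rbind(c(0.85, 0.15, 0.00),   # stage 0
                   c(0.35, 0.55, 0.10),   # stages 1-6
                   c(0.10, 0.65, 0.25),   # stages 7-12
                   c(0.00, 0.45, 0.55))   # stages 13-N
  dx <- vapply(seq_len(nX), function(j)
    sample(c("CN", "MCI", "AD"), 1L, prob = dx_prob[band[j], ]), "")

  cases <- data.frame(subject_id = sprintf("case%04d", seq_len(nX)),
                      baseline_diagnosis = dx,
                      age_years = stats::rnorm(nX, gs$age_mean[grp], gs$age_sd[grp]),
                      sex = ifelse(stats::runif(nX) < gs$male_prob[grp],
                                   "male", "female"),
                      apoe_e4_carrier = stats::runif(nX) < gs$apoe_prob[grp],
                      education_years = round(.truncated_normal(
                        nX, gs$education_mean[grp], gs$education_sd[grp], 6, 20)),
                      csf_abeta = .truncated_normal(
                        nX, config$amyloid_components[[1]]["mean"],
                        config$amyloid_components[[1]]["sd"],
                        lower = 0,
                        upper = cut_implied - config$amyloid_margin),
                      csf_ptau181 = NA_real_, wmh_ml = NA_real_,
                      wbv_ml = NA_real_, hip_ml = NA_real_,
                      tiv_ml = tiv_x, lm_score = NA_real_,
                      tmt_a_s = NA_real_, tmt_b_s = NA_real_,
                      hypertension = stats::runif(nX) < gs$hypertension_prob[grp],
                      stroke = stats::runif(nX) < gs$stroke_prob[grp],
                      lacune_present = stats::runif(nX) < gs$lacune_prob[grp],
                      cmb_present = stats::runif(nX) < gs$cmb_prob[grp],
                      stringsAsFactors = FALSE)
  cases <- .raw_from_aligned(cases, panel, Yx)
  cases <- .finalize_tmt(cases, Yx[, "tmt"], config)
  # physiological floors; only reachable under extreme noise draws
  cases$lm_score <- pmax(cases$lm_score, 0)
  cases$csf_ptau181 <- pmax(cases$csf_ptau181, 0.5)
  cases$followup <- .sample_followup(dx, band, config)

  truth <- data.frame(subject_id = cases$subject_id, subtype = subtype,
                      stage = stage, stringsAsFactors = FALSE)
  colnames(z_true) <- paste0("z_true_", panel$markers$name)
  zn <- z_noisy
  colnames(zn) <- paste0("z_", panel$markers$name)
  truth <- cbind(truth, as.data.frame(z_true), as.data.frame(zn))

  list(controls = cohort(controls, "reference_controls", "synthetic"),
       cases = cohort(cases, "cases", "synthetic"),
       truth = truth)
}

# construct a TMT A/B pair whose composite (after the 300 s part-B ceiling)
# equals the planted composite y, and exercise the ceiling flag when the
# drawn pair would exceed it
.finalize_tmt <- function(df, y, config) {
  n <- nrow(df)
  a <- .truncated_normal(n, config$tmt_a_mean, config$tmt_a_sd, lower = 5)
  a <- pmax(a, 1 - y + 1)          # keep part B positive for very low composites
  hit <- a + y > 300
  a[hit] <- pmax(300 - y[hit], 0.5)
  b <- pmin(a + y, 300)
  df$tmt_a_s <- a
  df$tmt_b_s <- b
  df$tmt_b_ceiling <- b >= 300
  df$tmt_comp <- pmin(b, 300) - a
  df
}

.sample_followup <- function(dx, band, config) {
  worse <- c(CN = "MCI", SMC = "MCI", MCI = "AD", AD = "AD")
  rate <- c(0, config$progression_rates)[pmin(band, 4L)]
  lapply(seq_along(dx), function(j) {
    if (stats::runif(1) < config$missing_followup_rate)
      return(data.frame(month = 36L, diagnosis = dx[j]))
    progressed <- dx[j] != "AD" && stats::runif(1) < rate[j]
    d6 <- dx[j]
    d12 <- if (progressed && stats::runif(1) < 0.5) worse[[dx[j]]] else dx[j]
    d24 <- if (progressed) worse[[dx[j]]] else dx[j]
    data.frame(month = c(6L, 12L, 24L), diagnosis = c(d6, d12, d24))
  })
}

#' Deterministic tiny fixture for exhaustive-enumeration tests
#'
#' A hard-coded 12-control / 20-case cohort over two plain markers with a
#' single z threshold each (N = 2 events, two valid orderings), small enough
#' that the exact posterior over sequences is enumerable. The planted
#' ordering is marker `m1` before `m2`.
#'
#' @return list with `controls`, `cases` ([cohort()]s), `truth` (subject id,
#'   stage), and `panel` (the 2-marker [marker_panel()]).
#' @export
make_tiny_fixture <- function() {
  panel <- marker_panel(name = c("m1", "m2"), column = c("v1", "v2"),
                        direction = "higher_is_worse",
                        z_thresholds = 1, z_max = 3)
  ctrl <- data.frame(
    subject_id = sprintf("tc%02d", 1:12),
    v1 = c(-1.5, -1.2, -0.9, -0.5, -0.2, -0.1, 0.1, 0.2, 0.5, 0.9, 1.2, 1.5),
    v2 = c(0.8, -1.4, 0.3, -0.6, 1.1, -0.2, 0.4, -1.0, 1.3, -0.8, 0.6, -0.5),
    stringsAsFactors = FALSE)
  # planted stages: 7 at stage 0, 7 at stage 1 (m1 abnormal), 6 at stage 2
  stage <- c(rep(0L, 7), rep(1L, 7), rep(2L, 6))
  v1 <- c(-0.22, 0.31, -0.05, 0.18, -0.41, 0.09, 0.02,
          1.12, 0.87, 1.31, 0.95, 1.24, 0.78, 1.05,
          3.21, 2.88, 3.05, 2.74, 3.32, 2.96)
  v2 <- c(0.11, -0.27, 0.35, -0.08, 0.22, -0.31, 0.04,
          0.41, 0.62, 0.38, 0.57, 0.49, 0.68, 0.52,
          3.11, 2.79, 3.24, 2.91, 2.85, 3.18)
  cases <- data.frame(subject_id = sprintf("tx%02d", 1:20),
                      v1 = v1, v2 = v2, stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = cases$subject_id, stage = stage)
  list(controls = cohort(ctrl, "reference_controls", "tiny fixture"),
       cases = cohort(cases, "cases", "tiny fixture"),
       truth = truth, panel = panel)
}

#' Score a fitted model against planted ground truth
#'
#' Matches fitted subtypes to planted subtypes by the label permutation that
#' maximises mean sequence agreement plus assignment accuracy, then reports:
#' normalised Kendall tau between each recovered and planted ordering
#' (rank correlation of event positions), subtype assignment accuracy among
#' truly staged (non-stage-0) cases — an unsubtyped or mislabelled case both
#' count as errors —, the Spearman correlation of recovered versus planted
#' stage within each subtype, and the absolute error of each mixture
#' fraction against the realised subtyped shares.
#'
#' @param model a [fit_sustain()] result.
#' @param assignments the matching [assign_subjects()] result.
#' @param truth the `truth` table from [generate_cohort()], aligned row-wise.
#' @param config the generating [synthetic_config()].
#' @return list with `permutation`, `kendall_tau`, `accuracy`,
#'   `stage_spearman`, `fraction_error`.
#' @export
score_recovery <- function(model, assignments, truth, config) {
  planted <- config$planted_sequences
  C <- length(planted)
  if (length(model$sequences) != C)
    stop("model and config disagree on the number of subtypes")
  ktau <- function(s1, s2)
    stats::cor(match(seq_along(s1), s1), match(seq_along(s2), s2),
               method = "kendall")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (r in perms(v[-i])) out <- c(out, list(c(v[i], r)))
    out
  }
  subtyped <- !is.na(truth$subtype)
  best <- NULL
  for (pm in perms(seq_len(C))) {
    taus <- vapply(seq_len(C), function(c_idx)
      ktau(model$sequences[[c_idx]], planted[[pm[c_idx]]]), numeric(1))
    mapped <- pm[assignments$ml_subtype]
    acc <- mean(!is.na(mapped[subtyped]) &
                  mapped[subtyped] == truth$subtype[subtyped])
    if (is.null(best) || mean(taus) + acc > best$score)
      best <- list(permutation = pm, kendall_tau = taus, accuracy = acc,
                   score = mean(taus) + acc)
  }
  pm <- best$permutation
  best$stage_spearman <- vapply(seq_len(C), function(c_idx) {
    i <- subtyped & !is.na(assignments$ml_subtype) &
      assignments$ml_subtype == c_idx & truth$subtype == pm[c_idx]
    if (sum(i) < 3) return(NA_real_)
    stats::cor(assignments$ml_stage[i], truth$stage[i], method = "spearman")
  }, numeric(1))
  realised <- vapply(seq_len(C), function(c_idx)
    mean(truth$subtype[subtyped] == pm[c_idx]), numeric(1))
  best$fraction_error <- abs(model$fractions - realised)
  best$score <- NULL
  best
}
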
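# assignment fixture: 5 subjects in groups (unsubtyped, s1, s1, s1, s2)
make_fake_assignment <- function(subtypes, stages) {
  structure(data.frame(subject_id = sprintf("f%02d", seq_along(stages)),
                       ml_subtype = subtypes, ml_stage = stages,
                       unsubtyped = stages == 0L),
            class = c("sustain_assignment", "data.frame"))
}

test_that("group summary books group sizes, WMH quantiles and shares", {
  df <- make_subject_df(5)
  df$wmh_ml <- c(1, 2, 4, 8, 16)
  df$baseline_diagnosis <- c("CN", "MCI", "MCI", "AD", "CN")
  ch <- as_cohort_df(df)
  a <- make_fake_assignment(c(NA, 1L, 1L, 1L, 2L), c(0L, 3L, 5L, 9L, 2L))
  s <- summarize_groups(ch, a)
  expect_equal(as.integer(s$n), c(1L, 3L, 1L))
  expect_equal(sum(s$n), n_subjects(ch))
  wmh1 <- s$continuous[s$continuous$group == "subtype1" &
                         s$continuous$variable == "wmh_ml", ]
  expect_equal(wmh1$value[wmh1$stat == "median"], 4)
  expect_equal(wmh1$value[wmh1$stat == "iqr"], IQR(c(2, 4, 8)))
  dx1 <- s$categorical[s$categorical$group == "subtype1" &
                         s$categorical$variable == "baseline_diagnosis", ]
  expect_equal(dx1$count[dx1$level == "MCI"], 2L)
  # the reported 7:93:45 diagnosis split corresponds to a 64% MCI share
  expect_equal(round(100 * 93 / (7 + 93 + 45)), 64)
  # 43 unsubtyped of 376 cases is an 11% share
  expect_equal(round(100 * 43 / 376), 11)
})

test_that("continuous contrasts reduce to the one-way regression F test", {
  set.seed(1)
  vals <- list(rnorm(20, 0), rnorm(20, 1), rnorm(20, 2))
  res <- compare_groups(vals, "continuous")
  oracle <- anova(lm(y ~ g, data = data.frame(
    y = unlist(vals), g = factor(rep(1:3, each = 20)))))
  expect_equal(res$statistic, oracle[["F value"]][1])
  expect_equal(res$p_value, oracle[["Pr(>F)"]][1])
  expect_error(compare_groups(list(rep(1, 5), rep(1, 5)), "continuous"),
               "degenerate")
})

test_that("Fisher exact p matches hypergeometric enumeration on 2x2 tables", {
  # direct enumeration oracle: sum of hypergeometric probabilities of tables
  # at most as probable as the observed one (two-sided)
  fisher_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    x_obs <- tab[1, 1]
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    sum(probs[probs <= dhyper(x_obs, m, n, k) * (1 + 1e-7)])
  }
  tabs <- list(matrix(c(3, 9, 7, 1), 2), matrix(c(2, 4, 5, 3), 2),
               matrix(c(10, 2, 4, 8), 2), matrix(c(1, 1, 1, 1), 2))
  for (tab in tabs) {
    expect_equal(compare_groups(tab, "categorical")$p_value, fisher_oracle(tab),
                 tolerance = 1e-7)
  }
  # proportional cells on equal margins carry no association
  expect_equal(compare_groups(matrix(c(5, 5, 5, 5), 2), "categorical")$p_value, 1)
})

test_that("Fisher enumeration oracle holds across all small 2x2 tables", {
  fisher_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  set.seed(2)
  for (rep in 1:50) {
    tot <- sample(6:40, 1)
    cells <- as.vector(stats::rmultinom(1, tot, rep(0.25, 4)))
    tab <- matrix(cells, 2)
    expect_equal(compare_groups(tab, "categorical")$p_value,
                 fisher_oracle(tab), tolerance = 1e-7)
  }
})

test_that("stage-marker correlation is exact on linear signals and near zero on noise", {
  stages <- rep(1:10, each = 3)
  n <- length(stages)
  a <- make_fake_assignment(rep(1L, n), stages)
  df <- data.frame(lin = 2 + 3 * stages, tiv = rnorm(n, 1433, 100))
  res <- stage_marker_correlation(a, df, 1, "lin")
  expect_equal(res$coefficient, 1)
  expect_equal(res$kind, "pairwise")

  set.seed(3)
  big_stages <- sample(1:18, 500, replace = TRUE)
  ab <- make_fake_assignment(rep(1L, 500), big_stages)
  dfb <- data.frame(noise = rnorm(500))
  resb <- stage_marker_correlation(ab, dfb, 1, "noise")
  expect_lt(abs(resb$coefficient), 0.1)

  # degenerate cases error
  expect_error(stage_marker_correlation(a, data.frame(cst = rep(1, n)), 1, "cst"),
               "constant marker")
  expect_error(stage_marker_correlation(a, df, 1, "lin", adjustment = "lin"),
               "fully explained")
})

test_that("semi-partial equals pairwise under an orthogonal covariate and removes shared variance", {
  stages <- rep(1:12, each = 4)
  n <- length(stages)
  a <- make_fake_assignment(rep(1L, n), stages)
  # covariate exactly orthogonal to the marker by construction
  cov_orth <- rep(c(-1, 1), n / 2)
  marker <- 5 + 0.8 * stages + rep(c(0.3, -0.3, -0.3, 0.3), n / 4)
  stopifnot(abs(cor(marker, cov_orth)) < 1e-10)
  df <- data.frame(m = marker, cv = cov_orth)
  plain <- stage_marker_correlation(a, df, 1, "m")
  semi <- stage_marker_correlation(a, df, 1, "m", adjustment = "cv")
  expect_equal(semi$coefficient, plain$coefficient, tolerance = 1e-9)
  expect_equal(semi$kind, "semi_partial")
  # an independent residual oracle
  res_or <- cor(resid(lm(m ~ cv, df)), stages)
  expect_equal(semi$coefficient, res_or)
})

test_that("diagnostic progression classifies by worst in-horizon diagnosis", {
  df <- rbind(
    make_subject_row("mci_prog", baseline_diagnosis = "MCI",
                     followup = "12:AD;24:AD"),
    make_subject_row("cn_late", baseline_diagnosis = "CN", followup = "36:MCI"),
    make_subject_row("mci_dip", baseline_diagnosis = "MCI",
                     followup = "6:CN;24:MCI"),
    make_subject_row("mci_rev", baseline_diagnosis = "MCI", followup = "12:CN"),
    make_subject_row("cn_stab", baseline_diagnosis = "CN", followup = "6:CN;24:CN"),
    make_subject_row("smc", baseline_diagnosis = "SMC", followup = "24:MCI"))
  ch <- as_cohort_df(df)
  a <- make_fake_assignment(c(1L, 1L, 1L, 2L, 2L, 2L), c(3L, 4L, 5L, 6L, 7L, 8L))
  pr <- progression_summary(ch, a, horizon_months = 24)
  st <- pr$status
  names(st) <- df$subject_id
  expect_equal(unname(st[c("mci_prog", "cn_late", "mci_dip", "mci_rev",
                           "cn_stab", "smc")]),
               c("progressed", "missing", "stable", "reverted", "stable",
                 "progressed"))
  # counts conserved per group x baseline diagnosis
  expect_equal(sum(pr$table[, c("stable", "progressed", "reverted", "missing")]),
               n_subjects(ch))
})

test_that("progression comparisons across synthetic groups run end to end", {
  g <- generate_cohort(synthetic_config(seed = 21, n_cases = 150))
  a <- make_fake_assignment(
    ifelse(is.na(g$truth$subtype), NA_integer_, g$truth$subtype),
    g$truth$stage)
  pr <- progression_summary(g$cases, a)
  # AD-baseline subjects fall outside the CN/MCI progression table
  n_cn_mci <- sum(g$cases$subjects$baseline_diagnosis %in% c("CN", "SMC", "MCI"))
  expect_equal(sum(pr$table[, c("stable", "progressed", "reverted", "missing")]),
               n_cn_mci)
  for (f in pr$fisher) if (!is.null(f)) expect_true(f$p_value >= 0 && f$p_value <= 1)
})
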
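# amypath

Subtype and stage inference for biomarker pathway heterogeneity in CSF
amyloid-positive cohorts.

Individuals on the Alzheimer's continuum do not become abnormal along one
canonical cascade: memory, tau, neurodegenerative and cerebrovascular
markers can deteriorate in different orders in different people. `amypath`
implements, as a tested and reusable R package, an analysis that uncovers
that heterogeneity from cross-sectional data:

1. **Amyloid gate** — a two-component Gaussian mixture fitted by EM to CSF
   amyloid-beta 1-42 values; the positivity cut-point is the 99th percentile
   of the amyloid-abnormal component. Values strictly below the cut-point
   define the case group; controls are amyloid-negative, APOE e4
   non-carrier, and stably cognitively normal.
2. **Normalisation** — six markers (logical memory, composite Trail Making
   Test, CSF p-tau181, log2 WMH volume, whole-brain and hippocampal volume)
   are direction-aligned and z-scored against the controls; WMH and the
   volumes as TIV-adjusted W-scores from a control-only regression.
3. **Subtype-and-stage model** — each subtype is an ordering `S` of the
   N = 18 events "marker m crosses z = 1, 2, 3". Given `S`, marker `m`'s
   expected value at stage `k` is piecewise linear through
   `(0, 0), (pos(m, z_r), z_r), (N, z_max = 5)`, and a subject's likelihood
   marginalises the stage uniformly:

   `p(x | S) = (1/(N+1)) * sum_k prod_m Normal(x_m ; mu_m(k | S), 1)`

   with a cohort modelled as a C-subtype mixture
   `p(x) = sum_c f_c p(x | S_c)`. Fitting combines multi-start greedy
   ascent over constrained orderings, hierarchical subtype splitting, and
   Metropolis-Hastings sampling for ordering uncertainty; the number of
   subtypes is selected by the cross-validation information criterion
   (CVIC) with a parsimony margin of 6.
4. **Evaluation** — per-group descriptive tables, linear-regression and
   Fisher-exact group contrasts, marker-stage (semi-partial) correlations,
   positional variance diagrams, and 24-month diagnostic-progression
   summaries.

Because the motivating cohort is access-restricted, the package ships a
seeded synthetic-cohort generator with planted ground truth
(`generate_cohort()`), so the entire pipeline is testable offline.

## Worked example

```r
library(amypath)

cfg <- make_paper_shaped_config(seed = 11)   # 86 controls, 376 cases, 3 subtypes
g   <- generate_cohort(cfg)

panel <- default_marker_panel()
ref   <- fit_control_reference(g$controls, panel)
Z     <- build_zscore_matrix(g$cases, ref, panel)

st <- sustain_settings(n_startpoints = 10, n_mcmc = 20000, burn_in = 2000,
                       thinning = 20, seed = 11, n_bisections = 6,
                       max_alternations = 50)
model <- fit_sustain(Z, panel, n_subtypes = 3, settings = st)
model
#> <sustain_model> 3 subtype(s), 18 stages, loglik -3983.773
#>   subtype 1 (fraction 0.266): wmh:1 > wmh:2 > wmh:3 > lm:1 > wbv:1 > lm:2 > ...
#>   subtype 2 (fraction 0.361): ptau:1 > ptau:2 > ptau:3 > lm:1 > lm:2 > hip:1 > ...
#>   subtype 3 (fraction 0.373): lm:1 > lm:2 > lm:3 > ptau:1 > hip:1 > ptau:2 > ...

a <- assign_subjects(Z, model)
table(a$ml_subtype, useNA = "ifany")
#>    1    2    3 <NA>
#>   92  126  138   20

score_recovery(model, a, g$truth, cfg)[c("kendall_tau", "accuracy")]
#> $kendall_tau
#> [1] 0.869 0.830 0.935
#> $accuracy
#> [1] 0.801
```

The fitted orderings recover the three planted progression pathways
(WMH-led, p-tau-led and memory-led; Kendall tau >= 0.83 against the planted
orderings after label matching), 80% of truly staged cases land in their
generating subtype, and the `NA` column is the unsubtyped group —
cases whose maximum-likelihood stage is 0, i.e. indistinguishable from the
control reference.

A single call runs everything, from cut-point to evaluation tables:

```r
pooled <- rbind(g$controls$subjects, g$cases$subjects)
run <- run_full_pipeline(list(cohort = cohort(pooled), n_subtypes = 3,
                              settings = st, out_dir = "results/run1"))
run$report$group_sizes
```

## Package layout

- `R/` — cohort I/O, amyloid gate, normalisation, model core, evaluation,
  synthetic data, pipeline orchestration
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/subtype-stage-inference.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design, limitations
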
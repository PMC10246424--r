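# myelodiv

Ecological-diversity analysis of tumor-infiltrating myeloid cells from bulk
transcriptomes, for computational oncologists and tumor-immunology groups who
have a labelled single-cell myeloid reference and bulk cohorts with clinical
follow-up.

Myeloid infiltrates (macrophage, monocyte and dendritic-cell subgroups) are
treated as an ecological community. Per sample, the package estimates
subgroup proportions `P_i` by non-negative least-squares deconvolution of
bulk expression against a single-cell-derived signature matrix, and
summarises the community with

```
Shannon index       H = -Σ P_i ln(P_i)        (primary index)
Gini–Simpson index      1 - Σ P_i²
Pielou evenness     J = H / ln(n)
```

It then relates `H` to outcomes (Cox PH with Breslow ties, Kaplan–Meier +
log-rank on quartile-extreme strata, logistic regression for treatment
response), contrasts the somatic mutation landscape between high- and
low-diversity patients (chi-square differential prevalence, Fisher
co-occurrence, overall and signature tumor mutation burden), detects
co-expression modules (soft-threshold adjacency, topological overlap,
module eigengenes), and distills the module most correlated with `H` into a
small-gene linear *surrogate diversity index* via random-forest permutation
importance, a greedy `|r| < 0.75` collinearity filter, and OLS. A synthetic
cohort generator with exact ground truth makes the whole pipeline testable
without restricted data.

## Worked example

```r
library(myelodiv)

cfg   <- simulation_config(n_bulk_samples = 500L, seed = 1L)  # 15 subgroups
sc    <- simulate_single_cell(cfg)          # labelled single-cell counts
bulk  <- simulate_bulk(cfg, sc$truth)       # noisy convex mixtures
clin  <- simulate_clinical(cfg, sc$truth)   # survival + response

sig <- build_signature(sc$counts, sc$labels,
                       select_markers(sc$counts, sc$labels, top_n = 5))
fr  <- to_fractions(deconvolve(bulk, sig))
dt  <- diversity_table(fr)
head(dt, 3)
#>       sample_id  shannon gini_simpson    pielou  n degenerate
#> S0001     S0001 1.879091    0.8103942 0.6938906 15      FALSE
#> S0002     S0002 2.255152    0.8699764 0.8327585 15      FALSE
#> S0003     S0003 1.674652    0.6792101 0.6183977 15      FALSE

clin$shannon <- dt$shannon[match(clin$sample_id, dt$sample_id)]
fit_cox(clin, "shannon")[, c("term", "hazard_ratio", "ci_lower",
                             "ci_upper", "p_value")]
#>      term hazard_ratio  ci_lower ci_upper    p_value
#> 1 shannon    0.6398273 0.4088992 1.001173 0.05060311

km <- km_logrank(clin, stratify_by_quantile(dt))
sprintf("log-rank chisq = %.2f, p = %.3g", km$chisq, km$p_value)
#> [1] "log-rank chisq = 4.61, p = 0.0318"
```

The generator plants `hazard_coefficient = -1` on *true* diversity (true HR
`exp(-1) ≈ 0.37` per unit Shannon index). The continuous estimate on
*deconvolved* diversity is attenuated toward 1 by estimation error
(HR 0.64 here, borderline at n = 500), while the quartile-extreme
Kaplan–Meier contrast is significant — a useful reminder that the index's
measurement noise matters when interpreting per-unit hazard ratios. (Cox on
the true planted diversity recovers β within Monte-Carlo error; that is what
the acceptance suite asserts.) A full end-to-end run — signature →
deconvolution → diversity → association → mutations → modules → surrogate
model, with a manifest of output checksums — is one call:

```r
run_all(load_config(), out_dir = "run1", simulate = TRUE)
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/myelodiv.R run-all --simulate --seed 1 --out run1
```

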
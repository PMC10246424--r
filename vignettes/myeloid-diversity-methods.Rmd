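---
title: "Myeloid infiltration diversity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myeloid infiltration diversity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelodiv)
```

## The problem

Tumor-infiltrating myeloid cells — macrophages, monocytes, dendritic cells —
are transcriptionally heterogeneous, and studies that track a single subtype
miss the composition of the whole compartment. `myelodiv` treats the myeloid
compartment of a bulk tumor transcriptome as an ecological community: it
estimates the proportions $P_i$ of $K$ myeloid subgroups in each sample by
reference-based deconvolution, then summarises each sample with community
diversity indices,

$$H = -\sum_{i=1}^{n} P_i \ln P_i, \qquad
  \text{Gini–Simpson} = 1 - \sum_{i=1}^{n} P_i^2, \qquad
  J = \frac{H}{\ln n}.$$

The Shannon index $H$ is the primary statistic: it up-weights rare
subpopulations, which matters immunologically because sparse antigen-presenting
populations can still be functionally decisive. Downstream, the package asks
whether $H$ predicts survival and treatment response, whether the somatic
mutation landscape differs between high- and low-diversity patients, and
whether a handful of genes can stand in for the whole deconvolution pipeline
(a "surrogate diversity index") in settings where single-cell references and
deconvolution are impractical.

## Deconvolution model

Bulk expression is modelled as a non-negative mixture $b \approx S x$, where
$S$ is a marker-gene $\times$ subgroup signature matrix built from labelled
single-cell data (arithmetic mean of untransformed expression per subgroup;
markers chosen by one-vs-rest log2 fold-change on log1p counts, ties broken
lexicographically). Each sample is solved independently by Lawson–Hanson
non-negative least squares in linear expression space ("absolute mode": the
raw coefficient vector). Proportions are $P_i = x_i / \sum_k x_k$; a sample
with an all-zero solution is flagged *degenerate* and carries missing
diversity rather than an imputed value.

The reference tool this replaces is a proprietary SVR-based service whose
exact behaviour cannot be reproduced bit-for-bit; NNLS is a transparent,
deterministic stand-in with the same mixture model. An SVR backend was
considered and dropped because no SVR implementation is available in the
supported dependency set; the `method` argument of `deconvolve()` therefore
accepts only `"nnls"`.

Pielou's $n$ is deliberately the *total* number of subgroups in the signature
(constant across samples), not the observed per-sample richness: evenness is
then comparable across samples. The observed-richness variant is available via
`diversity_table(pielou_n = "observed")`.

## Outcome association

Survival uses Cox proportional hazards (Breslow tie handling, Newton–Raphson
via the `survival` package) with the diversity index entering both
continuously (per-unit hazard ratio) and as quartile-extreme strata
(Kaplan–Meier + log-rank; the top and bottom quarter of patients, middle
excluded — `stratify_by_quantile()` also provides a median split because the
original analysis is ambiguous about its figure-level split). Treatment
response uses logistic regression on the z-scaled index, so odds ratios are
per SD. Hazard-ratio magnitudes are scale-dependent across cohorts; the
package reports both parameterisations and never asserts numeric equality
with any external cohort table.

Independent oracles back every fitted quantity in the test suite: a 1-D grid
search of the Breslow partial likelihood for Cox, hand-summed
observed-minus-expected statistics for the log-rank test, and the 2×2
cross-product identity for the saturated logistic model.

## Mutation landscape

Prevalence statistics are presence-based (a gene counts once per sample no
matter how many variants hit it; Silent-class variants excluded by default),
while mutation burden counts raw rows — prevalence is about samples, burden
about events. The per-gene 2×2 stratum-by-mutated table uses the chi-square
test (no Yates correction by default) with a Haldane–Anscombe +0.5 odds-ratio
correction when a cell is empty. The odds ratio is oriented so OR > 1 means
enrichment in the high-diversity stratum; the original report's OR orientation
is not recoverable from its text, so this package fixes and documents one
convention instead of guessing. Pairwise co-occurrence uses the two-sided
Fisher exact test among the 25 most prevalent genes (the reference
implementation's default depth), reported as signed $-\log_{10} p$. TMB
divides qualifying rows by a 38 Mb exome denominator (configurable); the
"signature TMB" panel is the union of each stratum's top-10 prevalent genes,
differential genes ($p < 0.01$), and genes in significant interactions.

## Co-expression modules and the surrogate model

`wgcna_lite` builds an unsigned adjacency $a_{ij} = |r_{ij}|^\beta$ with
$\beta = 8$, converts it to topological overlap, and clusters $1-\mathrm{TOM}$
by average linkage. A *static* cut at height 0.99 with a minimum module size
replaces the dynamic hybrid tree cut: the dynamic algorithm is large,
tangential to the scientific claim, and the planted-structure tests define
the acceptance surface here; `detect_modules(cutter = )` accepts an external
cutter for users who want the full algorithm. Eigengenes are first principal
components of the standardized module expression, oriented to positive mean
loading, and the module whose eigengene correlates best (significantly) with
$H$ is carried forward.

The surrogate model pipeline is: scale/center module genes; 70/30 split;
regression random forest (500 trees, mtry $=p/3$, bundled CART
implementation since no random-forest package is available in the supported
set); *permutation* importance on the held-out 30% (impurity importance is
biased toward high-cardinality features); union of the top-15 genes per
cohort; greedy collinearity filter dropping any gene with training
$|r| \ge 0.75$ against an already-kept, higher-importance gene; ordinary
least squares of $H$ on the z-scaled survivors. The fitted model stores its
training scaler, so scoring an external cohort is a deterministic affine map.
The published 5-gene panel (C3, CD27, GFPT2, GMFG, HLA-DPB1) ships as
`FIVE_GENE_PANEL`; its coefficients are cohort-specific and must be refit.

## The synthetic cohort: what it emulates and what it does not

All tests run against a generator with known ground truth
(`simulation_config()` defaults are the stated world; they were fixed before
the acceptance outcomes were measured and are not tuned):

* **Fractions.** $K = 15$ subgroups; per-sample fractions from a symmetric
  Dirichlet(0.5), sparse enough that true Shannon diversity varies widely.
* **Single cell.** Negative-binomial counts (dispersion 0.5) around
  log-normal baseline profiles; each subgroup's 5 markers sit 8× above their
  baseline elsewhere. Dispersion 0 gives a noiseless construction used by
  the exactness tests.
* **Bulk.** Exact convex mixtures `profiles %*% fractions` with
  multiplicative log-normal noise (sd 0.1, natural log).
* **Surrogate genes.** A convex mixture *cannot* carry a diversity signal
  under a symmetric mixing prior — by symmetry every fraction has the same
  covariance with $H$ and fractions sum to one, so any linear-in-fractions
  gene is asymptotically uncorrelated with $H$. The five planted surrogate
  genes are therefore a separate, documented layer: each gains 0.15 units of
  natural-log expression per SD of $H$ over a flat baseline. Against the 0.1
  log-noise this yields per-gene correlation with $H$ of about 0.83 and
  pairwise correlations of about 0.69 — *below* the 0.75 collinearity
  filter, which the published 5-gene panel must itself have satisfied to
  survive that filter. The mixture-exactness contract applies to marker and
  background rows only.
* **Survival.** Exponential event times with rate
  $0.1\,e^{\beta_{\mathrm{div}} H}$ ($\beta_{\mathrm{div}} = -1$ by default:
  higher diversity is protective, the direction the analysis is designed to
  detect; the magnitude is a free parameter, not an estimate of any real
  cohort). Censoring is independent exponential, with its rate solved so the
  expected censored fraction hits the configured 30%. An early draft
  censored uniformly *before* the event, which is informative and biased the
  Cox estimates — the acceptance criterion caught it.
* **Response.** Bernoulli with logit $-2 + 1 \cdot H$, giving a realistic
  minority responder fraction.
* **Mutations.** Ten panel genes mutate at exactly 0.4 (top-quartile
  diversity) vs 0.1 (otherwise). Five hundred background genes mutate at
  0.08 scaled by a per-sample log-normal propensity (sdlog 1, mean 1) —
  roughly 40 non-synonymous mutations per exome with the heavy right tail
  real breast-cancer cohorts show. That tail is what makes *all-gene* TMB
  insensitive to the planted panel effect while the *signature* TMB cleanly
  separates the strata, the qualitative contrast the analysis is meant to
  exhibit.

The generator does not emulate droplet artifacts (doublets, ambient RNA),
batch effects across platforms, subtype-linked diversity differences, or
correlated mutation processes. A green test therefore establishes that the
pipeline recovers what it is designed to recover under its own model
assumptions — not that any particular clinical cohort will reproduce the
original study's effect sizes, which derive from restricted-access data and a
proprietary deconvolution service.

## Numerical and procedural choices

* One global seed fans out to named per-component substreams (FNV-style
  string hash), so changing, say, the mutation parameters never perturbs the
  bulk matrix.
* NNLS tolerance scales with the signature's Frobenius norm; rank-deficient
  signatures warn and proceed (active-set solves fall back to a
  ridge-stabilised normal equation).
* ssGSEA uses integer-rank weights ($\alpha = 0.25$) by default, making
  scores invariant under monotone transforms; expression-value weights are
  available (`weight = "value"`). Expression ties break by descending gene
  ID; a set covering the whole universe scores 0 by convention.
* Stratification ties share the threshold side that keeps group sizes
  nominal, then break by sample ID. Degenerate samples are excluded, never
  imputed.
* `detect_modules()` defaults to `min_module_size = 30` (sensible for real
  cohorts with thousands of genes), but the *pipeline configuration* default
  is 5: the simulated demo cohort's coherent gene sets — 5 markers per
  subgroup and 5 surrogate genes — are 5-gene modules, and the default run
  should exercise every stage. Set `wgcna: {min_module_size: 30}` in the
  YAML for real data.
* Cox monotone likelihoods (separation) are flagged, never silently
  reported; the same for logistic separation.
* Monte-Carlo sizes in the acceptance suite follow the stated criteria
  except that surrogate recovery runs 25 replicates and the mutation
  contrast 20 (serial test budget); the pass thresholds are unchanged.

## Known limitations

* No cross-platform signature adjustment (the proprietary tool's batch
  modes); cross-platform robustness is explicitly out of scope.
* The static tree cut can split a weakly connected module that the dynamic
  cut would keep; module *counts* are therefore not comparable to WGCNA
  output, only planted-structure recovery is asserted.
* Fisher interaction testing is capped at the top 25 genes; exhaustive
  pairwise testing over thousands of genes is out of scope.
* The random forest is a compact CART ensemble, not a drop-in replacement
  for `randomForest`; only ranking behaviour (not importance magnitudes) is
  contracted.
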
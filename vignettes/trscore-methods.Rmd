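---
title: "Methods: weighted-median risk scores, FFPE refinement, and their validation"
author: "trscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-median risk scores, FFPE refinement, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trscore)
```

# The model

`trscore` is built around a simple, robust per-sample statistic. Given a
cohort whose expression has been normalized and gene-wise z-scored
(`normalize_log`, `standardize_genes`), and a signature assigning each gene
a weight $w_g$ (its combined log hazard ratio from training cohorts), the
transcriptomic risk score of sample $k$ is

$$\mathrm{TRS}_k = \operatorname{median}_{g \in S}\; w_g\, z_{gk},$$

the median over the weighted standardized expression values. The median
(mean of the two central values for even-sized sets) makes the score
insensitive to a minority of aberrant genes — important when signatures are
applied to cohorts where only part of the gene panel is measured, or where
individual genes are corrupted by platform or preservation artifacts.
Samples with $\mathrm{TRS}_k > 0$ are labeled increased-risk; the boundary
value 0 belongs to the reduced-risk group.

Two deliberately different variants exist alongside the weighted median:

- the **simplified score** $\operatorname{median}(z_{gk}: w_g>0) -
  \operatorname{median}(z_{gk}: w_g<0)$, used for cross-signature
  benchmarking where published panels report only effect directions. Note
  that this is a genuinely different statistic from the TRS even when all
  weights are $\pm 1$: the TRS is the median of one pooled signed set, the
  simplified score a difference of side medians (they coincide exactly only
  for one-sided signatures). Both are exposed, and the benchmark applies the
  simplified score to *every* signature — including the package's own — so
  comparisons are fair.
- the **per-cell score**, a difference of unweighted means over risk and
  protective genes. Single-cell data have high dropout and shallow per-gene
  coverage, which makes training weights meaningless at the cell level;
  dropping them is the documented design choice, and no dropout imputation
  is attempted.

## Survival layer

All survival machinery delegates to the `survival` package: Cox partial
likelihood with Efron tie handling (Newton–Raphson, convergence tolerance
1e-9, 50 iterations), Kaplan–Meier with Greenwood variance and log-log 95%
intervals, the two-group Mantel–Haenszel log-rank test, and Harrell's
concordance with score ties counted 1/2. Choices the underlying literature
leaves open are fixed as follows:

- **Ties**: Efron by default. One consequence, verified in the tests, is
  that case-weight identities (e.g. duplicating every sample at half
  weight) hold only approximately under Efron, because duplication creates
  ties that Efron resolves by death count; `fit_cox(ties = "breslow")` is
  available where exact weight identities matter.
- **Monotone likelihoods**: a fit with $|\log HR| > 10$ or a non-convergence
  warning is flagged `converged = FALSE` and excluded from downstream gene
  rankings, never silently reported.
- **Grade adjustment**: Gleason Grade Group enters the multivariable model
  as the indicator GGG > 2, which splits the dominant Gleason-7 group into
  3+4 versus 4+3; a continuous Gleason-score covariate is the documented
  alternative.
- **Curve truncation**: the conventional rule of truncating displayed curves
  once fewer than 10 patients remain at risk in every group is reported as
  `truncation_time` but never applied to estimation.

## FFPE refinement

Formalin fixation degrades RNA over storage time, so genes whose measured
expression correlates with specimen age carry storage information that can
masquerade as (or drown) prognosis. `refine_signature` removes, in order of
precedence:

1. **age-associated genes** — per-gene simple linear regression of
   normalized expression on specimen age, two-sided slope test, flagged at
   p < 0.1. The liberal threshold is intentional: a falsely removed clean
   gene costs a sliver of signal, a retained degraded gene poisons the
   score. Regression on normalized (pre-z-score) expression keeps slopes in
   interpretable units; z-scoring would rescale slope and SE identically
   and leave the p-value unchanged.
2. **externally unvalidated genes** — univariate Cox per gene in an
   independent external cohort; kept only if p < 0.1 *and* the sign matches
   the training weight. Genes absent from the external cohort cannot be
   validated and are removed (conservative).

Tumor-cell-content and sequencing-depth screens are available as
diagnostics but are off by default: in our validation experiments they do
not improve prognostic accuracy, and every removal shrinks the panel.
Crucially, neither filter touches the FFPE cohort's own endpoint, so the
refined signature can be validated on that same cohort without circularity.

## Random-gene-set null

A signature's Cox p-value in a validation cohort is compared against the
p-values of `B = 1000` random gene sets of exactly the size of the
signature's overlap with that cohort, drawn without replacement from the
pool of genes that (i) entered the training meta-analysis, (ii) are not in
the signature, and (iii) passed the cohort's expression filter. Each random
gene keeps its own training logHR as weight, so the null preserves the
score's construction, not just its size. The empirical p-value uses the
add-one rule $(1 + \#\{p_b \le p_{obs}\})/(B+1)$, which is never zero and
valid at finite $B$. Sets may overlap across draws (draws are independent);
the seed is a required argument.

## Meta-analysis

Per-gene effects (survival logHR, or logistic log-OR for Gleason score > 7)
are estimated cohort by cohort on standardized expression, then combined
with inverse-variance random-effects weights $1/(SE_i^2 + \tau^2)$. REML is
the default $\tau^2$ estimator (via `metafor`); the DerSimonian–Laird
closed form is implemented independently and doubles as the fallback when
REML fails at small $k$. Genes must appear in at least two cohorts;
duplicate patients across cohorts can be down-weighted $1/N$ when a
multiplicity map is available. P-values are Wald (the convention is stated
because the combined-effect test convention is otherwise ambiguous); FDR is
Benjamini–Hochberg per endpoint.

## Cell-compartment analyses

Differential expression between lineages (or between cell types within a
lineage) is patient-averaged: cells are never treated as replicates.
Expression is averaged per patient per side, and a two-sided Wilcoxon
rank-sum test compares the patient means (exact where tie-free), with
BH-FDR within each contrast; significance requires FDR < 0.05 and log fold
change > 0.25. Marker selection uses the diagnostic odds ratio on detection
counts (expression > 0) in a 2×2 table with Haldane +0.5 correction — our
operationalization of detection-specificity metrics; thresholds DOR > 2 and
log2 FC > 1 for lineage markers, DOR > 1 for tumor-specific luminal
markers. Spot-level module scores subtract an expression-matched background:
genes are binned by average expression (24 quantile bins) and 100 control
genes are drawn, seeded, per set gene.

# The synthetic study

The generator exists so that every claim above is testable against known
truth. `simulate_bulk_cohort` draws gene baselines $\mu_g \sim U(2,10)$,
$\sigma_g \sim U(0.5,1.5)$ on the log scale and expression
$x_{gk} = \mu_g + \sigma_g \varepsilon_{gk}$; the linear predictor
$\eta_k = \sum_g \beta_g \varepsilon_{gk}$ runs over a configured set of
prognostic genes with $|\beta| $ drawn from `effect_size_range` and random
signs; event times are exponential with hazard
$\lambda_0 e^{\eta_k}$, and independent exponential censoring is tuned by
bisection so the expected censored fraction hits `censor_rate` (within
about 0.02). FFPE degradation is modeled as additive per-gene drift
`slope × specimen_age` applied *after* outcome generation — a pure
confounder, uncorrelated with survival. Specimen ages are uniform on
1–18 years, a wide range consistent with archival biopsy collections whose
median storage approaches a decade; no empirical degradation curve is
imposed because none is established, so slope magnitudes are free
parameters. Prognostic and age-affected gene sets are disjoint by default
(an `allow_overlap` flag lifts this), so recovery experiments have
unambiguous truth. Multi-cohort collections share all gene-level truth and
add per-cohort mean offsets and random gene panels; cohort $i$ draws its
samples under seed `seed + 1000·i`, making every cohort reproducible in
isolation.

What the generator does *not* emulate: read-level sequencing noise,
batch-correction scenarios, copy-number structure, non-proportional
hazards, or informative censoring. Tests passing on these simulations
demonstrate that the *procedures* behave as designed under their stated
assumptions — not that any particular clinical cohort satisfies those
assumptions.

## A caution on effect attenuation

One empirical property of the simulations deserves emphasis because it is a
real phenomenon, not an artifact. When many genes jointly drive the hazard
(say 50 genes with $|\beta| \in [0.3, 0.6]$, total linear-predictor
variance ≈ 10), each *univariate* Cox fit estimates the gene's marginal
association, which is attenuated relative to the generative coefficient —
Cox models are non-collapsible, and high-risk patients leave the risk sets
early. In our experiments the attenuation is close to proportional (rank
correlation with truth ≈ 0.98 among prognostic genes), so screening,
direction calls and meta-analytic ranking are unaffected, but confidence
intervals for the *conditional* coefficients do not — and cannot — attain
nominal coverage in that regime. Interval calibration is therefore
evaluated where the marginal and conditional effects coincide (a single
prognostic covariate), and the multi-gene experiments assert recovery of
ranks and directions, or use small per-gene effects
($|\beta| \in [0.05, 0.15]$) where total heterogeneity is low and
attenuation negligible. Users interpreting per-gene meta-analytic logHRs on
real data should read them the same way: as marginal, not causal-joint,
effects.

## The degradation-contrast scenario

The package's flagship qualitative result — an unrefined signature failing
on FFPE material while its refined version succeeds — is reproduced by a
designed scenario: a 100-gene signature of which 10 genes are truly
prognostic (weights equal to their true logHRs), 60 are degradation-prone
with zero true effect and drift slopes of 0.4–0.8 expression units/year
whose sign aligns with the gene's training weight, and 30 carry arbitrary
weights with no effect anywhere. The alignment choice models the realistic
failure mode in which training weights and degradation both track overall
transcript abundance and fragility, and it gives the weighted median a
systematic specimen-age component that drowns the minority of real signal.
On a 176-sample FFPE-like cohort the full signature's TRS is then not
significantly associated with outcome while the refined signature (age
filter removes the drifting block; the external filter, run on a clean
300-sample cohort sharing the same truth, removes the arbitrary-weight
block) is strongly associated. The acceptance suite requires this contrast
in at least 16 of 20 seeded replicates.

# Default parameters at a glance

| Parameter | Default | Where | Why |
|---|---|---|---|
| IQR filter cutoff | 0.25 | `iqr_filter` | drop the least variable quartile of genes |
| Age-filter alpha | 0.1 | `refine_signature` | liberal removal of degradation-prone genes |
| External-filter alpha | 0.1 | `refine_signature` | nominal external evidence plus sign consistency |
| DGEA thresholds | FDR < 0.05, LFC > 0.25 | `patient_averaged_dgea` | standard pseudobulk significance |
| DOR cuts | 2 (lineage), 1 (T-luminal) | `dor_markers` | detection-specificity of markers |
| Random sets | B = 1000 | `null_distribution` | empirical p resolution 1/(B+1) |
| Module score bins / controls | 24 / 100 | `module_enrichment` | expression-matched background |
| Censoring target tolerance | ±0.02 | generator | bisection stopping rule |
| Cox convergence | tol 1e-9, 50 iter | `fit_cox` | survival-package Newton–Raphson |
| REML | tol 1e-8, 100 iter, DL fallback | `random_effects_combine` | small-k robustness |

The pipeline defaults (`default_pipeline_config()`) simulate 300 genes with
30 prognostic, two training cohorts of 300 samples, three validation
cohorts of 150, a 176-sample FFPE-like cohort with 60 age-affected genes,
and a 300-sample external cohort; signature inclusion requires
meta-analysis FDR < 0.05. Training size and prognostic count were chosen
together so that, given marginal-effect attenuation, the trained signature
recovers a meaningful fraction of planted genes; the test and acceptance
suites use these and smaller problem sizes as their standard working scale.

# Numerical and degenerate-input policy

- Errors are classed conditions (`invalid_config`, `no_overlap`,
  `degenerate_covariate`, `empty_pool`, ...), so callers can react
  programmatically; warnings flag recoverable states (signature overlap
  below 50%, skipped cohorts, non-convergent fits).
- Quantiles (IQR threshold) use linear interpolation between order
  statistics (R type 7), z-scores the $n-1$ SD; both affect only constant
  scalings of the score, not its dichotomization at 0 asymptotically.
- Benchmark ranks break p-value ties lexicographically by signature name so
  reruns are reproducible; signatures with no overlap in a cohort get NA
  cells and are excluded from that cohort's ranking.
- All randomness flows from explicit integer seeds; sub-streams derive from
  a master seed by fixed offsets. `run_validation` writes byte-identical
  outputs on reruns with the same config.

# Known limitations

- The variance stabilizer is library-size scaling + log2(x+1); cohort-wise
  z-scoring makes downstream scores insensitive to this choice, but
  low-count genes are not shrunk as a dedicated variance-stabilizing
  transform would.
- Per-gene meta-analytic effects are marginal associations (see the
  attenuation note); no joint or penalized multivariable estimation is
  offered.
- The age filter is univariate; if specimen age correlated with a clinical
  covariate in a real archive, the filter would remove genes tracking
  either.
- Cell-compartment analyses assume lineage/cell-type labels arrive as
  metadata; clustering, integration and annotation are out of scope.
- No time-varying covariates, competing risks, or proportionality
  diagnostics.
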
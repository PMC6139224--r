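---
title: "Methods: integrating DNA methylation and expression to find methylation-regulated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating DNA methylation and expression to find methylation-regulated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medegs)
```

# The scientific problem

DNA methylation at CpG sites, particularly in promoters, can silence or
modulate transcription. In a case–control design with both a β-value
methylation matrix and an expression matrix on the same samples, genes
whose expression change runs opposite to their methylation change
(up-regulated + hypomethylated, or down-regulated + hypermethylated) are
candidate *methylation-regulated* differentially expressed genes (MeDEGs).
`medegs` implements the complete chain from raw numeric matrices to a
classified MeDEG table and SVM-based diagnostic panels, together with a
synthetic cohort generator that plants all of the structure the analysis
assumes, so that every stage can be validated against known truth.

# Statistical models and assumptions

## Differential expression

Each probe is fitted by ordinary least squares:

$$y_{ij} = \beta_0 + \beta_g\,\mathrm{case}_j + \beta_a\,\mathrm{age}_j +
\beta_s\,\mathrm{sex}_j + \beta_1\,\mathrm{PC1}_j + \beta_2\,\mathrm{PC2}_j
+ \varepsilon_{ij}$$

with $y$ on the log2 scale. The group coefficient $\beta_g$ is the
covariate-adjusted log2 fold change; its $t$-statistic (df $= n - 6$)
gives the two-sided p-value, BH-adjusted across probes. We deliberately
use a plain per-probe OLS $t$-test rather than an empirical-Bayes
moderated variance: at $n \approx 37$ the moderation gain is modest, and
the plain test has exactly known null behaviour, which the calibration
tests exploit (the null false-positive rate at raw $p<0.05$ must sit at
$5\% \pm 1\%$). The linear fold change is the back-transformed
coefficient, $\mathrm{sign}(\beta_g)\,2^{|\beta_g|}$, so the effect filter
and the p-value come from the same model rather than from a raw
group-mean ratio.

The principal-component covariates are the sample scores on the first two
axes of the probe-centred expression matrix, computed on *all* probes
before any filtering. They stand in for population-stratification and
composition effects. A consequence worth stating: PCs are only sensible
covariates when the dominant global variance is *not* the group contrast.
The synthetic generator therefore includes two global background factors
(loadings $\sim N(0, 0.2)$ per probe) that dominate the top of the
spectrum exactly the way stratification does in real cohorts; without
them the top PCs align with the planted group axis and adjusting for them
would absorb the signal itself. Users applying the pipeline to data with
no such structure should pass `covariates = NULL` or drop the PC columns.

Transcript-to-gene collapse keeps the probe with the largest absolute
fold change (ties: smaller adjusted p, then probe ID), and DEG calls
require adjusted $p < 0.05$ **and** $|FC| > 1.5$, both strict.

## Differential methylation

β values are compared between groups with the Wilcoxon rank-sum test —
robust at these sample sizes and making no distributional assumption
about β, which is bounded and often skewed. The effect size is the
difference of group *medians*, $\Delta\beta$, with DMPs requiring
BH-adjusted $p < 0.05$ and $|\Delta\beta| > 0.12$, both strict. The exact
permutation p-value is used for pooled sizes up to 12 without ties; above
that, the normal approximation with tie and continuity corrections.

A rank test cannot adjust for covariates. Because covariate-adjusted
methylation analysis is sometimes wanted, `test_differential_methylation`
offers an `"ols"` mode fitting logit(β) with the same design as the
expression model (PCs, if used, computed on logit β); the default remains
the unadjusted rank-sum test. Probe filtering removes any probe with a
detection p-value above 0.01 in *any* sample — the strictest reading,
chosen to keep matrices complete rather than introducing per-cell
missingness — and all chrX/chrY probes, since both sexes are analysed
together.

## Genomic annotation

Coordinates are 0-based, intervals half-open (BED convention),
everywhere. A CpG maps to the gene with the nearest TSS when the unsigned
distance is strictly below 10 kb (equidistant ties: lexicographically
smallest gene ID). Region classification is strand-aware with the 450K
precedence order TSS200 > TSS1500 > 5'UTR > 1stExon > 3'UTR > Body; CpG
context uses the platform's standard bands (shore ≤ 2 kb from an island
boundary, shelf ≤ 4 kb, open sea beyond). The same nearest-TSS map serves
both the DMP-to-gene collapse and the integration pairing; a platform
annotation could disagree for distal probes, and swapping in such a map
only requires replacing the `mapping` argument.

## Integration and MeDEG classes

For each gene present on both platforms, Pearson correlations are
computed for every expression-probe × methylation-probe pair across *all
pooled samples* — cases and controls together. Pooling is the only
reading that yields one correlation per pair and it maximizes power for
the between-group coupling the analysis seeks; the cost is that a pooled
correlation partly reflects the group contrast itself, which is why the
MeDEG *class* is defined by the signs of the fold change and
$\Delta\beta$ (as in the summary tables), with the max-|r| pair's
correlation reported as supporting evidence rather than as the
classifier. Genes whose best pair has undefined correlation (zero
variance) are excluded with a message. The selected DMP's region decides
the `promoter_dmp` flag (TSS1500/TSS200/5'UTR/1stExon).

The package does not require the max-|r| methylation probe to coincide
with the gene's significant DMP: the pairing is evidence, the calls are
calls. A stricter analysis can intersect the two by filtering the pair
table on the DMG probe IDs.

## Diagnostic panels

The radial-kernel SVM follows the standard protocol: for every
(cost, gamma) on log2 grids ($2^{-5}\dots2^{15}$ and $2^{-15}\dots2^3$,
steps of ×4), full leave-one-out cross-validation is run with features
standardized *inside* each training fold (constant features get unit
scale), and the grid point with the best accuracy is kept — ties prefer
the smallest cost, then the smallest gamma, i.e. the smoother model. Grid
points that can no longer strictly beat the incumbent are abandoned
mid-LOOCV; because the scan order equals the tie-preference order, this
pruning cannot change the selected model. Greedy forward selection adds
whichever candidate maximizes LOOCV accuracy (ties: lexicographic name)
and stops at perfect accuracy, at `max_size`, or when no addition
improves accuracy, making the accuracy path non-decreasing; an exhaustive
mode evaluates all subsets up to `max_size` for ≤ 30 candidates.

Tuning happens on the same LOOCV that is reported, which matches the
customary small-cohort protocol but is optimistic: on pure-noise features
the tuned, selected accuracy sits well above the majority rate (around
0.6–0.7 at $n = 37$ in our null experiments). `search_feature_panel`
therefore warns whenever the final accuracy is within two binomial
standard errors of the majority rate, and a perfect-separation claim
should always be read as "perfect under this protocol", not as an
unbiased error estimate. Nested cross-validation is deliberately out of
scope.

Hierarchical clustering uses 1 − Pearson distance with average linkage
(the common choice for array heatmaps), cut at two clusters;
misclassification counts take the better of the two cluster-to-group
mappings, making them invariant to cluster relabelling.

## Downstream stages

Gene-set enrichment is a one-sided upper-tail hypergeometric test against
an explicit background with BH correction — a generic replacement for
curated commercial tools, so its p-values are comparable only within a
fixed gene-set collection. Clinical-subgroup contrasts (e.g. ILD vs
non-ILD cases) use the rank-sum test at raw $p < 0.05$, uncorrected, as
is conventional for small exploratory subgroup analyses; this is a
liberal choice and is flagged as such. qPCR relative quantities follow
$2^{-\Delta\Delta C_t}$.

# The synthetic cohort generator

`sim_config()` defaults describe the study conditions the pipeline
targets: 18 cases vs 19 controls; 2000 genes with 2 expression probes
each (the designated first probe carries the full planted effect, the
second an attenuated ×0.5 effect, exercising the max-|FC| collapse); 5000
CpG probes spread over all gene-region and CpG-context categories on a
synthetic linear chromosome; 100 planted DEGs at ±1.0 log2 FC with noise
sd 0.3; 150 planted DMPs at ±0.20 median Δβ with logit-scale noise sd
0.3; 25 coupled MeDEG genes (20 inverse, 5 positive — 60% of coupled
probes in promoter categories); 1% of probes with a failed detection
p-value; 2% of probes on sex chromosomes; ages $\sim N(43, 10)$, balanced
sex, and an ILD flag on 10 cases. Effect sizes sit comfortably above the
calling thresholds because the generator's role is structural validation,
not power analysis; all values are configurable.

β values arise as the inverse logit of Gaussian latents. This makes group
shifts and coupling compose additively on the latent scale while keeping
β strictly inside (0, 1), and the latent shift for a planted DMP is
solved exactly from the probe's baseline so that the *population median*
β difference equals the target (baselines for planted probes are drawn in
(0.3, 0.6) so a ±0.2 shift never saturates). A Beta-distributed
alternative would not compose additively.

Coupling is implemented as a correlation-preserving mixture: for a
coupled gene with per-sample factor $f_j \sim N(0,1)$ and loading
$\rho$ (default 0.8), the noise on each layer is
$\mathrm{sd}\,(\pm\rho f_j + \sqrt{1-\rho^2}\,e_j)$, with the sign
negated on the methylation side for the inverse class. The marginal noise
sd is therefore *unchanged* — coupled probes are exactly as detectable as
uncoupled ones — while the cross-layer noise correlation is $-\rho^2$
(inverse) or $+\rho^2$ (positive); together with the aligned group
shifts, the pooled per-gene correlation centres near −0.9 for inverse
genes (Monte-Carlo over the generative model). An additive factor with a
fixed coefficient would instead inflate the per-probe variance and make
coupled genes systematically harder to detect than uncoupled ones, which
would confound recovery benchmarks.

What the generator does **not** emulate: raw array intensities, dye bias,
batch effects, normalization artefacts, cell-type composition on the
methylation layer, spatial correlation of neighbouring CpGs, or realistic
effect-size distributions. Passing recovery tests therefore demonstrates
the pipeline's correctness on data satisfying its assumptions — not
performance on any real cohort.

# Numerical and design choices

- **BH adjustment** is `stats::p.adjust(method = "BH")` behind a
  validated wrapper; tests check it against a literal step-up oracle.
- **Zero-variance probes** get $p = 1$ and zero effect rather than
  errors, so pipelines never abort on constant rows; zero-variance
  *pairs* are excluded from correlation pairing with a message.
- **Singular designs** (e.g. a covariate confounded with group) abort
  with the collinear column named.
- **Tie-breaks** are total and documented at each stage (probe collapse:
  |effect|, then adjusted p, then probe ID; TSS ties: gene ID; pairing
  ties: more negative r, then probe IDs; grid ties: smallest cost then
  gamma; greedy ties: lexicographic feature name), making every result
  deterministic given the seed.
- **Sign convention for PCs**: the largest-magnitude probe loading is
  made positive, so scores are reproducible across runs and platforms.
- **Detection-failure filtering** removes whole probes, never single
  cells, keeping all matrices complete.

# Problem sizes used in the test suite

The acceptance battery runs the full default-scale pipeline (2000 genes /
5000 CpGs / 37 samples) over 20 seeds for planted-signal recovery, 100
reduced null cohorts (300 genes / 600 CpGs) for calibration — sizes at
which the Monte-Carlo standard error of the estimated false-positive rate
is well below the ±1% acceptance band — and one 37-sample panel search on
the default grids. Module-level property tests use small random instances
(pooled rank-sum sizes ≤ 10, backgrounds ≤ 10 genes, ≤ 5×5 probe pairs)
where brute-force enumeration oracles are exact.

# Known limitations

- The OLS expression test assumes approximately Gaussian residuals on the
  log2 scale; heavy-tailed arrays would warrant a robust variant.
- Pooled correlations conflate within-group coupling with the group
  contrast (discussed above); an eQTM-style within-group analysis is out
  of scope.
- LOOCV accuracy with in-loop tuning is optimistic; treat panel
  accuracies as protocol-relative.
- The enrichment stage is database-agnostic and will not reproduce any
  specific curated tool's p-values.
- Nearest-TSS mapping ignores transcript isoforms; genes are single-TSS
  models.
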
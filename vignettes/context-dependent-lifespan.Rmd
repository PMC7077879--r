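---
title: "Context-dependent quantitative genetics of life span with ctxlife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent quantitative genetics of life span with ctxlife}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxlife)
```

## The problem

Life span in *Drosophila melanogaster* panels such as the Genetic Reference
Panel (DGRP) is measured on replicated inbred genotypes ("lines") in both
sexes and several thermal environments.  Because each genotype is observed
many times, the data support questions that are impossible in outbred
cohorts: how much of the variation is genetic; whether the *same* genotypes
are long-lived in both sexes and at all temperatures (genotype-by-sex, GSI,
and genotype-by-environment, GEI, interaction); and whether genotypes differ
not only in their mean life span but also in its *variability* across
genetically identical flies (micro-environmental variance).  `ctxlife`
implements this analysis stack, together with the complementary
pooled-sequencing extreme-QTL (xQTL) mapping design used in an outbred
population derived from the same panel, and a synthetic-data generator that
emulates both experiments.

## The mixed model and its derived statistics

Individual life span is modelled with the cross-classified mixed ANOVA

$$Y = \mu + L + S + T + L{\times}S + L{\times}T + S{\times}T +
L{\times}S{\times}T + Rep(L{\times}T) + S{\times}Rep(L{\times}T) + \varepsilon,$$

with sex ($S$) and temperature ($T$) fixed, line ($L$) and all
line-containing interactions random, and replicate vials ($Rep$) nested in
line-by-temperature.  `fit_variance_components()` estimates the variance
components by REML through `lme4::lmer`, whose boundary-constrained
optimization guarantees non-negative components (convergence is lme4's
default, relative tolerance around 1e-8); unbalanced data — including whole
missing line-by-temperature cells — are handled natively and nothing is
imputed.  Reduced models (per temperature, per sex, per cell) drop the
non-identifiable terms.  Likelihood-ratio tests for random terms use the
standard boundary correction (an equal mixture of $\chi^2_0$ and
$\chi^2_1$); Wald chi-squared tests are reported for fixed terms because the
exact denominator degrees of freedom of the historical F-tests are not
well defined for unbalanced mixed models.

`derive_genetics()` turns a component set into the familiar summaries:

* $H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_\varepsilon)$, with
  $\sigma^2_G$ the sum of all line-containing components of the fitted
  model.  The phenotypic denominator deliberately excludes the replicate-vial
  components, following the convention of the reference analysis; since it
  is arguable whether vial variance belongs in $\sigma^2_P$, the
  vial-inclusive alternative is reported as `h2_incl_vial`.
* $CV_G = 100\,\sigma_G/\bar X$ and
  $CV_\varepsilon = 100\,\sigma_\varepsilon/\bar X$, with $\bar X$ the
  average of the two sex means in the analyzed context.
* cross-sex, cross-temperature and overall genetic correlations
  $r_{GMF} = \sigma^2_L/(\sigma^2_L+\sigma^2_{LS})$,
  $r_{GT} = \sigma^2_L/(\sigma^2_L+\sigma^2_{LT})$,
  $r_{GST} = \sigma^2_L/(\sigma^2_L+\sigma^2_{LS}+\sigma^2_{LT}+\sigma^2_{LST})$.
  These are ratios of non-negative components and so live in $[0,1]$.

```{r}
derive_genetics(c(sigma2_L = 354.38, sigma2_LS = 84.98, sigma2_eps = 689.24),
                means = c(F = 77.86, M = 84.97))
```

### Rank change versus scale change

An interaction variance between two contexts $A$ and $B$ can exist for two
qualitatively different reasons: genotypes change rank order between the
contexts, or the among-genotype variance changes scale.
`decompose_interaction()` separates the two:

$$\sigma^2_{int} = \underbrace{\sigma_A\sigma_B(1-r)}_{\text{rank change}}
 + \underbrace{(\sigma_A-\sigma_B)^2/2}_{\text{scale change}},$$

an exact algebraic identity with
$\sigma^2_{int} = (\sigma_A^2+\sigma_B^2)/2 - r\sigma_A\sigma_B$ (tested to
machine precision).  The rank share `pct_rank` is reported as `NA` — not 0
or 100 — when both terms vanish ($\sigma_A=\sigma_B$, $r=1$), since the
ratio is then genuinely undefined.  For more than two contexts,
`decompose_interaction_multi()` averages the pairwise terms, matching the
multi-environment definition of $\sigma^2_{LT}$.

```{r}
decompose_interaction(20.51, 21.40, 0.806)   # GSI of life span at 18 C
```

## Micro-environmental variance

The variance phenotype of a genotype is
$\ln\sigma_\varepsilon = \ln\sqrt{S^2}$, with $S^2$ the unbiased sample
variance of life span over all flies of a (line, sex, temperature,
replicate-group) cell.  Replicate groups come from
`split_replicate_groups()`, which pools the first half of the vials as group
1 and the second half as group 2 (12/12 for a 24-vial panel; 24/24 for a
48-vial knockdown assay); cells that cannot be split into equal halves are
dropped with a warning rather than silently kept.  Vials are *pooled*, not
averaged, so the phenotype includes between-vial as well as within-vial
variation — both are micro-environmental from the genotype's point of view.
Zero-variance groups are flagged and excluded because their log is
undefined.  The resulting table feeds straight back into
`fit_variance_components(include_vial = FALSE)`, giving heritabilities and
context correlations of the variance phenotype itself.

Two classical tests ask whether within-line variances are heterogeneous at
all.  `brown_forsythe()` performs the one-way ANOVA on absolute deviations
from the line *median* (ties at the median are handled by the standard
sample median; nothing special is done for even $n$).  `cochran_c()`
computes $C = \max_j S^2_j/\sum_i S^2_i$; because the reference analysis
reports p-values without stating a method, the package uses the classical
critical-value relation
$C_{crit} = [1 + (k-1)/F_{\alpha/k}(\nu,(k-1)\nu)]^{-1}$ with $\nu$ the
average within-group degrees of freedom, inverted at the observed statistic.
Simulation shows this p-value is well calibrated at the experimental scale
($k \approx 180$, $n \approx 64$; type-I error 0.05 within Monte-Carlo
error).  Brown–Forsythe — which the test suite verifies to be
identical to the standard one-way ANOVA on median-centred absolute
deviations — is by contrast inherently conservative at moderate group
sizes (type-I error below half the nominal level at $n = 64$ in the null
simulations); it approaches the nominal level only for groups of about 200
flies or more.  The acceptance suite asserts nominal
calibration at large $n$ and non-anti-conservatism at experimental $n$.

## Line-mean association scans

`derive_phenotypes()` builds the full set of contrast phenotypes per line:
sex means, sex average, sex difference (fixed orientation male minus
female), temperature-pair differences (higher minus lower), and the sex
difference of each temperature difference.  Fixed orientations make effect
signs comparable across modules.  `marker_scan()` residualizes the phenotype
on fixed covariates (Wolbachia infection, inversion karyotypes) and then
regresses the residual on each variant's dosage — the standard two-step
approximation used in large scans; at typical covariate counts the
difference from a joint fit is negligible.  The original study additionally
adjusted for polygenic relatedness with a mixed model whose pipeline
internals are not public; the package replaces this with the fixed-covariate
adjustment (leading genotype principal components can be supplied as
covariates where relatedness control is needed).  Variants are oriented to
the minor allele at scan time and filtered at MAF > 0.05; missing dosages
are dropped per variant.  `classify_effects()` labels reported variants as
context-specific, antagonistic, or concordant across contexts and reports
Spearman effect correlations and LD ($r^2$) among reported variants.

## Pooled-sequencing xQTL tests

In the outbred design, the longest-lived 10% of an aged cohort (96 of 960
flies per sex, temperature and replicate) are sequenced as a pool and
compared with a same-size pool of random young flies.  The package models a
pool frequency estimate with two sampling stages — 192 chromosomes into the
pool, then reads from the pool:

$$\mathrm{Var}(\hat f) = \tilde f(1-\tilde f)
 \left(\tfrac{1}{2n_{pool}} + \tfrac{1}{reads}\right),$$

where $\tilde f = (alt+0.5)/(reads+1)$ is used inside the variance only, so
that a variant fixed among sampled reads does not get zero variance (the
point estimate stays unmoderated).  The literature the reference analysis
cites does not print its variance formula; this standard pool-seq model is
the package's documented choice, and Monte-Carlo simulation of the two-stage
sampling matches it within 10%.  `z_test_hc()` averages
$\Delta f = \hat f_H - \hat f_C$ over replicates with model-based variance
(the empirical between-replicate variance is reported as a diagnostic only —
two replicates are too few to estimate it stably), and refers
$Z = \bar{\Delta f}/\sqrt{\mathrm{Var}}$ to the standard normal.
`cross_context_z()` contrasts $\bar{\Delta f}$ between independent cohorts
(sexes, temperature pairs, or sex-by-temperature) with summed variances.
The reporting threshold defaults to $p < 10^{-7}$; the Bonferroni
annotation uses the analyzed variant count rather than any hard-coded
genome-wide value.  `antagonism_summary()` classifies variants across the
six sex-by-temperature analyses and counts, per gene, pairs of significant
variants with opposite $\Delta f$ — within a context, across temperatures,
across sexes, and across both.

## Gene-length-corrected enrichment

Longer genes collect more variants, so naive enrichment tests are biased
toward long-gene categories.  `go_enrichment()` draws, `n_perm` times, a
random gene set of the observed size *without replacement with probability
proportional to gene length* (base R's `sample(prob = )` performs exactly
the sequential draw-remove-renormalize scheme) and scores each GO term by
$p = (B+1)/(N+1)$, which is seed-reproducible and never smaller than
$1/(N+1)$.  Gene length is the gene-body length from the gene model (the
definition of "length" is not fixed by the reference analysis; transcript
length can be substituted by supplying different lengths).  Annotations are
used as given — no GO-graph ancestor propagation.  The naive hypergeometric
p-value is reported alongside, and Benjamini–Hochberg FDR across terms for
both.  In simulations with length-biased candidate sets the naive test
produces spurious FDR-significant long-gene terms while the weighted
permutation does not — the qualitative behaviour that motivates the
correction.

## The synthetic-data generator

`simulate_lifespan_panel()` is the generative inverse of the mixed model:
one record per fly, with life span = context mean + line + line-by-sex +
line-by-temperature + line-by-sex-by-temperature + vial + residual.  Key
choices:

* **Defaults emulate the reference panel**: 186 lines, 3 temperatures, 2
  sexes, 24 vials of 3 flies/sex (72 flies/sex/line/temperature); whole
  line-by-temperature cells dropped for 3/186 lines at 18 °C and 9/186 at
  28 °C, mirroring poor viability at extreme temperatures; sex-by-temperature
  means of 77.9/85.0, 41.6/44.2 and 27.2/26.8 days.
* **Genetic components** default to $\sigma^2_L = 30$,
  $\sigma^2_{LS} = 13$, $\sigma^2_{LT} = 38.1$, $\sigma^2_{LST} = 15.8$
  days², chosen so that a single-temperature analysis recovers among-line
  and line-by-sex variances near the published 25 °C values (68 and 29
  days²) with $r_{GMF} \approx 0.70$, $r_{GT} \approx 0.44$ and
  $r_{GST} \approx 0.31$.  Vial variance, which the reference tables do not
  print, is set to 4 days².
* **Heritable micro-environmental variance** arises from a log-normal
  line-specific residual SD: a fly's residual SD is
  $\exp(\mu_{\ln\sigma}[s,t] + a_L + b_{LS} + c_{LT})$ with per-context
  means equal to the published $\ln\sigma_\varepsilon$ means (3.2, 2.45,
  2.14) and line-level spreads from the published variance components of the
  variance phenotype.  This makes $\ln\sigma_\varepsilon$ itself heritable
  on exactly the scale the analysis uses.  (Note the implied *average*
  residual variance is inflated above $e^{2\mu}$ by the log-normal factor
  $e^{2\sigma^2_{\log}}\approx 1.24$.)
* **Truncation**: life spans below 1 day are set to 1 day, the observed
  minimum in the reference data.  The floor distorts moments when the mean
  is within ~3 SD of it, which matters only for deliberately extreme
  parameter choices.

The xQTL arm (`simulate_founder_genotypes()`, `simulate_aip_cohort()`,
`pool_select_and_sequence()`) draws individual genotypes per variant from
founder allele frequencies — i.e. linkage equilibrium.  The statistics under
test are all per-variant, so LD realism is deliberately out of scope;
consequences are that the generator cannot exercise LD-based clumping or
haplotype reconstruction, and passing tests say nothing about those.
Control pools are fresh draws from the founder frequencies ("young flies"
collected independently of the aged cohort), matching the experimental
design and the independence assumption of the Z test.  Read counts are
binomial at a per-pool, per-variant depth drawn uniformly from 130–156×,
with no sequencing-error model beyond binomial sampling.  The residual
(environmental) life span SD of the outbred cohort is not determined by the
reference study and is exposed as the free parameter `sigma_env` (default
12 days, of the order of the within-line SD of the panel at 25 °C).

What the generator does *not* emulate: survival-curve shapes (lifespans are
Gaussian around the genotype mean, not Gompertz), age-dependent mortality,
recombination and selection over generations, Wolbachia/inversion
covariates, and sequencing error.  Tests passing on synthetic data therefore
validate the estimators and their calibration, not robustness to those
real-data features.

## Numerical choices and problem sizes

* REML fits use lme4 defaults; degenerate inputs (constant response) return
  an explicit all-zero, flagged fit instead of an optimizer failure.
* The test suite's REML-recovery study uses 186 lines × 3 temperatures × 2
  sexes × 6 vials × 2 flies/sex/vial (about 13,000 records per replicate, 50
  replicates) with a homoscedastic residual, so each true component is known
  exactly; each component must fall within twice its Monte-Carlo standard
  error in at least 90% of replicates.
* Calibration studies use 10,000 variants (within-context Z), 5,000
  (cross-context), 1,000 null replicates (variance-heterogeneity tests), and
  permutation sizes of 400–4,000 for enrichment; these sizes give
  Monte-Carlo error comfortably inside the asserted bands.
* All simulation entry points take a `seed` and are bit-reproducible;
  `run_pipeline()` records the seed and package version in a manifest and in
  every TSV header.

## Known limitations

* Variance-component standard errors are not reported (lme4 does not expose
  them); inference on random terms uses likelihood-ratio tests instead.
* The polygenic-relatedness adjustment of the original line-mean scans is
  approximated by fixed covariates (optionally genotype PCs); scans on
  strongly structured panels will be less well calibrated than the original
  mixed-model pipeline.
* Brown–Forsythe is conservative at typical per-line sample sizes (see
  above); Cochran's C p-values rely on the classical approximation and an
  *average* group size under unbalance.
* The enrichment module treats annotations as flat labels; topology-aware
  GO methods are out of scope.
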
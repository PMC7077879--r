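# ctxlife

Context-dependent quantitative genetics of life span in replicated inbred
panels and outbred pooled-sequencing designs.

## What it is for

Panels of fully inbred, sequenced *Drosophila* lines (DGRP-style) measure
each genotype's life span many times — in both sexes and in several thermal
environments.  `ctxlife` is for geneticists analyzing such designs who want
to answer, with tested code:

* How much of the variation in life span is genetic, per context
  (broad-sense heritability *H²*, coefficients of genetic and environmental
  variation)?
* Do the same genotypes live long in both sexes and at all temperatures
  (cross-context genetic correlations; genotype-by-sex and
  genotype-by-environment interaction)?  And is an interaction variance due
  to genotypes *changing rank* between contexts or to the genetic variance
  *changing scale*?
* Is the within-line (micro-environmental) variance of life span itself
  heritable (the ln σε variance phenotype, Brown–Forsythe and Cochran's C
  heterogeneity tests)?
* Which variants are associated with these phenotypes — via line-mean scans
  with sex/temperature contrast phenotypes in the panel, and via pooled
  sequencing of extreme long-lived versus control pools (xQTL Z tests) in an
  outbred population — and are their effects context-specific, concordant,
  or antagonistic?
* Are candidate gene sets enriched for GO terms once the length of genes
  (and hence their a-priori chance of harbouring a hit) is corrected for?

A synthetic-data generator emulates both experimental designs with known
truth, so every stage is testable without external data.

## The core statistics

For a pair of contexts with genetic standard deviations σ_A, σ_B and
cross-context genetic correlation r, the interaction variance decomposes
exactly as

    σ²_int = σ_A σ_B (1 − r)   +   (σ_A − σ_B)² / 2
             └─ rank change ─┘     └─ scale change ─┘

with *H²* = σ²_G / (σ²_G + σ²_ε), r_GMF = σ²_L / (σ²_L + σ²_LS), and
analogous cross-temperature and overall correlations.  The xQTL side tests
Δf = f_H − f_C per variant with a two-stage binomial variance
f(1−f)(1/(2·pool) + 1/reads), and contrasts Δf across sexes and
temperatures with independent-cohort Z tests.  GO enrichment draws null
gene sets without replacement with probability proportional to gene length
and scores terms by p = (B+1)/(N+1).

## Worked example

```r
library(ctxlife)

# simulate a 60-line panel (8 vials x 3 flies/sex/vial, 3 temperatures)
d <- simulate_lifespan_panel(
  panel_design(n_lines = 60, vials_per_line_per_temp = 8),
  true_components(), seed = 1)

# variance components at 25 C, both sexes
fit <- fit_variance_components(subset(d, temperature == "25"),
                               model = "by_temperature", lrt = FALSE)
fit
#> REML variance components (by_temperature model, response: lifespan_days)
#>       sigma2_L      sigma2_LS    sigma2_vial sigma2_sexvial     sigma2_eps
#>        76.0601        27.8087         0.0000        14.7706       142.5853

derive_genetics(fit)
#> sigma2_G sigma2_P       H2     CV_G   CV_eps    r_GMF
#> 103.8688 246.4542   0.4215  23.2510  27.2419   0.7323
```

About 42% of the phenotypic variance at 25 °C is genetic (*H²* = 0.42);
the cross-sex genetic correlation r_GMF = 0.73 says female and male line
means are similar but far from identical, i.e. there is genuine
genotype-by-sex interaction.  (The vial component sits at the REML boundary
in this draw — lme4 flags such fits as singular; with only 60 lines the
small vial variance is hard to separate from its sex-split counterpart.)
Decomposing a published sex-by-line interaction:

```r
decompose_interaction(20.51, 21.40, 0.806)
#>   sigma_a sigma_b     r rank_term scale_term interaction_variance pct_rank
#>     20.51    21.4 0.806  85.14932    0.39605             85.54537 99.53703
```

99.5% of that interaction variance is rank-order change: which genotypes
are longest-lived differs between the sexes, rather than one sex simply
being more variable.

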
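# gutmaturity

Tools for analysing gut microbiome maturation in longitudinal pediatric
cohorts with inflammatory bowel disease (IBD), including very early onset
IBD (VEO-IBD, onset before age 7). The package is aimed at microbiome
researchers who have species-level relative-abundance tables (shotgun
taxonomic profiles) and per-sample clinical metadata for children spanning
a wide age range, and who want to separate the effects of *age* from the
effects of *inflammation* on the gut community.

## What it computes

* **Diversity and dysbiosis** — richness, Shannon diversity (nats),
  Bray-Curtis dissimilarity `BC(x, y) = 1 − 2·Σmin(xᵢ, yᵢ)/(Σxᵢ + Σyᵢ)`,
  and a per-sample dysbiosis score: the median Bray-Curtis distance to a
  reference panel of healthy children aged ≥ 7 years (own-subject samples
  excluded).
* **Longitudinal per-taxon testing** — a zero-inflated beta regression with
  subject random effects: a logistic presence sub-model and a beta
  abundance sub-model, each with a Gaussian subject intercept integrated
  out by Gauss–Hermite quadrature; a combined likelihood-ratio test of the
  group effect across both sub-models with Benjamini–Hochberg FDR control.
* **Microbiota maturity index (MMI)** — a Random-Forest regression of
  chronological age (months) on species abundances, trained on 70% of
  antibiotic-free healthy controls; species ranked by repeated permutation
  importance; panel size chosen by nested subject-level cross-validation.
  The healthy test set calibrates a smoothing spline of MMI versus age, and
  each sample's **Relative MMI** is
  `RMMI = MMI − spline(age)` (months; negative = reduced maturity).
* **Healthy-constrained mixture** — a two-component model of MMI versus
  age: one component frozen at the healthy spline, a reduced-maturity line
  through a convergence point at the youngest ages whose slope, residual
  scales and mixing weight are estimated by EM; per-sample posterior
  membership with 0.25/0.75 confidence bands and visit-to-visit component
  switching.
* **Evaluation** — rank-based ROC/AUC of RMMI as a disease classifier,
  Spearman correlations, and rank-test group summaries.
* **Synthetic cohorts** — `generate_cohort()` simulates a four-group
  longitudinal study (healthy under/over 7, VEO-IBD, pediatric IBD; ~195
  subjects, 3 visits) with known ground truth: age-maturation trajectories,
  configurable maturity delays (defaults 25 and 55 months), dysbiosis
  markers, antibiotic effects, and calprotectin/human-DNA biomarkers, so
  the whole pipeline can be validated against recoverable truth.

## Worked example

```r
library(gutmaturity)

co  <- generate_cohort(cohort_config(seed = 42))
mod <- fit_maturity_model(co$taxa, co$samples, n_repetitions = 100, seed = 43)
mmi <- predict_mmi(mod, co$taxa, co$samples)
res <- merge(mmi, co$samples, by = "sample_id")

mean(res$rmmi_months[res$group == "HC_ge7"]) -
  mean(res$rmmi_months[res$group == "PIBD"])
#> [1] 56.0   # recovered pediatric-IBD maturity delay (truth: 55 months)

rmmi_roc(res$rmmi_months, res$group %in% c("VEO", "PIBD"))
#> roc_result: AUC = 0.980 (320 positive, 249 negative)
```

The recovered group-mean RMMI difference estimates the simulated
55-month maturation delay of the pediatric IBD group, and the AUC measures
how well low relative maturity separates disease from healthy samples in
this synthetic cohort.

A full run — simulate, filter, diversity, taxon tests, maturity, mixture,
evaluation, with per-stage TSV outputs and an MD5-digest manifest — is:

```r
run_pipeline(cohort_config(seed = 7), "out/", seed = 7)
```

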
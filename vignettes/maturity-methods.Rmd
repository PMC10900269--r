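---
title: "Methods: microbiota maturity and dysbiosis in pediatric IBD cohorts"
author: "gutmaturity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiota maturity and dysbiosis in pediatric IBD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gutmaturity` analyses longitudinal stool metagenomic profiles of children
with inflammatory bowel disease (IBD), including very early onset IBD
(VEO-IBD, onset before age 7), against age-matched healthy controls. The
package covers: a synthetic cohort generator with known ground truth;
taxa-table input and the two species filters used throughout; alpha
diversity, Bray-Curtis beta diversity and a healthy-reference dysbiosis
score; per-taxon longitudinal testing with a zero-inflated beta regression
with subject random effects (ZIBR); a Random-Forest microbiota maturity
index (MMI) with nested cross-validated panel selection and a
spline-normalised Relative MMI (RMMI); a healthy-constrained two-component
mixture model; and rank-based evaluation (ROC/AUC, Spearman, group
summaries). `run_pipeline()` chains the stages under one master seed.

# The synthetic cohort generator

Real shotgun profiles of such a cohort require controlled-access raw reads
and cluster-scale taxonomic classification. The generator instead emulates
the *post-classification* data — species relative-abundance tables plus
sample metadata — with enough statistical structure that every downstream
method is exercised against a known truth.

**Study design.** Four groups (healthy controls under/over 7 years, VEO-IBD,
pediatric IBD) sampled at weeks 0, 4 and 8; defaults of 63/20/58/46
longitudinal subjects plus 8 older cross-sectional VEO subjects, matching a
typical single-centre pediatric IBD cohort (~195 subjects, ~570 samples).
Enrolment ages are truncated normals per group (HC\<7 43±20, VEO 52±21,
HC≥7 149±43, pediatric IBD 171±35 months) — the demographic profile of such
cohorts, where young groups centre near age 4 and older groups in
adolescence.

**Abundance kernel.** Per-species log abundance is
`baseline + trajectory(effective age) + marker/antibiotic terms + subject
intercept + visit noise`, exponentiated, zero-inflated, then closed to sum
one. Zeros are applied *before* closure, so they are structural — the
assumption the ZIBR model downstream makes. Maturation trajectories are
saturating curves `A·s(a)` with `s(a) = (a/(a+τ))/(R/(R+τ))` normalised at
the age-range maximum `R = 228` months: every maturation species realises
its full amplitude over the observed range regardless of timescale.
Decreasing (infancy-associated) species draw short timescales, increasing
(adult-associated) species long ones, reflecting that adult-type anaerobes
keep accumulating through childhood while infancy taxa fade early.

Three anchoring choices matter and were made deliberately:

* **Peak anchoring.** A maturation species' *peak* abundance (adult level
  for increasing, infant level for decreasing species) sits at its drawn
  baseline. Without this, increasing species grow `e^A`-fold and come to
  dominate total community mass, so after compositional closure *every*
  bystander taxon's share declines with age; any disease or antibiotic
  depletion of bystanders then masquerades as increased maturity. With
  equal numbers of increasing and decreasing species anchored at their
  peaks, community mass is age-stable and bystander shares stay flat.
* **Marker anchoring.** Disease markers are rare pathobionts in health
  (baseline minus the dysbiosis effect) that bloom *to* ordinary levels in
  disease, rather than ordinary taxa blooming beyond them — again keeping
  the closure from converting marker blooms into spurious age signal.
* **Presence coupling on the normalised shape.** Presence log-odds move by
  a bounded swing (default 3 logits) over the trajectory shape, not by the
  full abundance amplitude; maturation shows in prevalence without driving
  species extinct (prevalence of declining taxa stays detectable, as in
  real data where infancy taxa persist at low abundance).

**Disease effect.** The maturity delay is a shift of the age axis:
disease-group samples express the community of `effective age = age −
delay` (floored at zero), with defaults of 25 months (VEO) and 55 months
(pediatric IBD). This makes "delayed maturation" a single recoverable
parameter. Disease samples additionally bloom marker species and lose a
fraction of fragile taxa; antibiotic-exposed samples zero a fraction of the
fragile pool and suppress the survivors by 2 logs. Concentrating both
losses on one fragile pool mirrors the preferential depletion of
oxygen-sensitive commensals in IBD and under antibiotics, and keeps the
perturbation off the maturation panel itself except through closure.

**Noise regime.** Visit noise 0.2 and subject intercepts 0.2 logs,
baseline spread 1.0 log, amplitudes 5–8 logs. This is a deliberately
high-signal regime: it reproduces the tight healthy MMI-versus-age fit such
studies report (held-out Spearman ≈ 0.97, residual ≈ 15–20 months). During
design we verified with oracle panels and linear-model ceilings that under
substantially stronger subject-level noise the Random-Forest prediction
slope against true age shrinks (approximately by the local R²), and a
25/55-month delay is then *not* recoverable by any species panel — the
failure would be a property of the regime, not of the estimator. Passing
recovery tests on this generator therefore demonstrates correctness of the
pipeline, not that delays of this size are identifiable in arbitrarily
noisy real cohorts.

**Biomarkers.** Fecal calprotectin is lognormal around 25 µg/g (healthy)
and 220 µg/g (disease; ≈46% above the 250 µg/g activity threshold at
baseline), declining on newly started therapy. Stool human-DNA percentage
is generated from the same latent inflammation scale through a Gaussian
copula with rank correlation 0.46. New-therapy subjects also receive
per-visit jitter of the maturity delay (SD 15 months), making their
component membership less stable across visits than maintenance-therapy
subjects.

What the generator does **not** emulate: strain-level structure, functional
(gene-ortholog) profiles, realistic heavy-tailed abundance distributions
(baseline spread is kept moderate to bound closure noise), sequencing depth
variation, or age-assortative antibiotic indication.

# Filters and diversity

Species present in fewer than 20% of the samples entering a comparison are
removed (presence means abundance strictly above zero; exactly 20% is
retained). Before maturity modelling, species whose maximum abundance is at
or below 0.01% (1e-4 as a fraction) are removed. Filtered tables are *not*
renormalised, so diversity on full tables and tests on filtered tables stay
consistent; both filters are idempotent and commute.

Richness counts species with nonzero abundance; Shannon diversity uses the
natural log over renormalised nonzero entries. Bray-Curtis dissimilarity is
`1 − 2·Σmin(x,y)/(Σx+Σy)`. The dysbiosis score of a sample is its *median*
Bray-Curtis distance to the reference panel of antibiotic-free healthy
children aged ≥7 years, excluding the sample's own subject; the median
follows the Integrative Human Microbiome Project convention and is robust
to single outlying references (a mean aggregator is available). Stability
is summarised by all pairwise Bray-Curtis distances among a subject's
visits and their mean.

# Longitudinal per-taxon testing (ZIBR)

Each taxon is modelled by two sub-models sharing a design matrix
(group, age, antibiotic use, visit week): logistic presence and, for
present samples, beta-distributed abundance in mean/precision (µ, φ)
parameterisation with a logit link. Each sub-model carries an independent
Gaussian subject random intercept integrated out by Gauss–Hermite
quadrature (9 nodes by default; estimates change by <1e-3 when refined to
17 on test fixtures), and is maximised by box-constrained quasi-Newton.
Because the sub-models share no parameters, the joint likelihood
factorises; the combined group test is the sum of the two likelihood-ratio
statistics against the nested null with group terms removed, referred to a
chi-square with the summed degrees of freedom. Component-wise tests are
reported alongside. If a full-model component ever fits worse than its
nested null (a failed optimisation), it is refit starting from the null
optimum before testing. Degenerate taxa fall back to the informative
sub-model: all-present taxa drop the logistic component, mostly-absent taxa
drop the beta component. Abundances of exactly 1 are nudged to `1 − 1e-6`.
q-values are Benjamini–Hochberg over all converged taxa within one
comparison; non-converged fits are excluded from the family with a message.
The comparison of VEO-IBD with pediatric IBD excludes antibiotic-exposed
VEO subjects, because no pediatric IBD subject is exposed.

# The maturity index

Training uses antibiotic-free healthy controls only, split 70/30 at
*subject* level (all of a subject's visits on one side), stratified within
each control group by age tertile so both sides span the range. Species are
ranked by mean permutation (out-of-bag) importance of a regression forest
of chronological age on relative abundances, repeated (default 1000 times;
the pipeline and test suite use 100, which changes top ranks by at most a
couple of positions) on baseline-visit samples, with lexicographic
tie-breaks. Panel size is chosen by nested cross-validation: outer 5-fold
subject-level CV, importance re-ranked inside each fold, candidate sizes by
successive halvings plus a fine grid around the coarse minimum, squared
error of predicted versus chronological age, ties to the smaller panel.

The final forest is trained on all training samples restricted to the
selected panel. Forests used for final models and CV scoring use
`mtry = ⌈p/2⌉` and terminal nodes of 2: with the regression default
(`p/3`, nodesize 5) the prediction bias at the ends of the age range is
visibly larger and flattens recovered delays; importance ranking keeps the
randomForest defaults. MMI predictions for training samples use the
forest's out-of-bag values — in-sample predictions are overfit and would
sit systematically above the spline calibrated on held-out samples.

The healthy spline maps age to expected MMI on the held-out healthy
samples. Smoothness is chosen by leave-one-subject-out cross-validation
over an effective-degrees-of-freedom grid (3–8): each subject contributes
three correlated visits, which makes pointwise generalised
cross-validation overfit badly (df ≈ 15 and erratic extrapolation);
GCV remains the fallback when no subject structure is supplied. Beyond the
observed age range the natural spline continues linearly, with a warning.
`RMMI = MMI − spline(age)`; negative values mean reduced maturity.

# The two-component mixture

MMI versus age is modelled as a two-component Gaussian mixture. Component 1
is the frozen healthy spline (never re-estimated). Component 2 is a line
constrained through a convergence point at the youngest fitted age, where
healthy and delayed trajectories coincide; a free-intercept variant is
available. EM estimates only the reduced slope, two residual scales and the
mixing weight; the log-likelihood trace is checked non-decreasing, and ten
restarts (first deterministic, rest random slopes) keep the best
likelihood, with convergence at 1e-6 or 500 iterations. Posterior
membership uses Bayes' rule on the two Gaussian densities; bands are
`confident` outside (0.25, 0.75) and `uncertain` inside, boundaries
inclusive on the uncertain side. Visit-to-visit switching uses hard labels
at 0.5 and is summarised by therapy stratum. Degenerate fits (all mass on
one component) are returned with a warning rather than an error.

# Evaluation

AUC uses the Mann–Whitney rank formulation with midrank ties; the RMMI
classifier is oriented so that lower RMMI scores as more diseased.
Per-cohort AUCs are computed on the HC≥7 ∪ pediatric-IBD and HC\<7 ∪ VEO
subsets. Group comparisons use rank tests (Wilcoxon rank-sum, or
signed-rank when paired) with median/IQR summaries; where repeated visits
would pseudo-replicate, tests are run on subject means.

# Reproducibility and problem sizes

A single master seed fans out to per-stage seeds through a documented
arithmetic rule (`derive_seed`), so any stage can be re-run in isolation;
the pipeline writes a manifest with MD5 digests of every output, and two
runs under one seed are digest-identical. The test suite runs the
generator at full cohort size; model fits use 100 importance repetitions,
25 within CV folds, and 20 replicates for null-calibration checks —
problem sizes chosen so the full suite completes in minutes while leaving
the conclusions unchanged (ranking repetitions beyond 100 move top ranks
by at most a couple of positions on this generator).

# Known limitations

* The generator's low-noise regime demonstrates estimator correctness, not
  identifiability under arbitrary real-world noise (see above).
* The ZIBR sub-models assume independent subject intercepts; their
  correlation is not modelled.
* The beta sub-model is moderately misspecified for closed log-normal
  abundances; calibration of the combined test on the null generator is
  verified empirically rather than guaranteed.
* RMMI inherits the forest's boundary bias at the extremes of the age
  range; the spline removes it for healthy-like samples but recovered
  delays attenuate slightly near the boundaries.
* No phylogeny-aware metrics, no functional profiles, no linear
  mixed-effects modelling of dissimilarity, and at most three visits per
  subject in the ZIBR machinery.
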
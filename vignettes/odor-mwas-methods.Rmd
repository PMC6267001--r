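---
title: "Methods: associating skin-microbiome features with odor intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: associating skin-microbiome features with odor intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinmwas)
```

## The analysis problem

Body-odor intensity is a continuous, perfumer-scored phenotype (0–100)
measured per subject, body site and timepoint. The question the workflow
answers is which microbial species, enzymes (KEGG-orthology groups, KOs)
and metabolic pathways co-vary with that phenotype, in a cohort of
pre-pubescent children and teenagers sampled at the underarm, neck and
head, once 1 h after a shower and once 8 h later after exercise. Two
complementary views of association are combined:

* **cross-sectional** — Spearman's rank correlation between a feature's
  relative abundance and odor intensity over a site's samples, with both
  timepoints pooled (two samples per subject; within-subject dependence is
  deliberately ignored, keeping a single interpretable coefficient per
  stratum);
* **longitudinal** — a Wilcoxon signed-rank test on subject-paired 1 h vs
  8 h abundances, asking which features shift with sweat production.

Both tests run in three age strata — children, teenagers, and the pooled
"youth" — and p-values are Benjamini–Hochberg adjusted **within each
(site, stratum, test) family** across features, mirroring the per-stratum
adjusted p-values of species summary tables in this literature. A feature
is called significant when its adjusted cross-sectional p is below 0.1
*and* |ρ| exceeds 0.2. The |ρ| (rather than signed ρ) gate is a deliberate
choice: negative associations (odor-suppressed commensals) are as
reportable as positive ones, and strata that report ρ = −0.45 as
significant only make sense under an absolute-value reading. The
direction arrow is the sign of the median paired (8 h − 1 h) difference;
an exact zero median renders "none".

Functional association runs in two modes. The **bag of genes** pools each
gene family's community total regardless of which species contributed the
reads; the **bag of genomes** keeps the per-(gene family, species) strata
of a taxonomically stratified profile. After mapping gene families to KOs
(one KO per family; one or more pathways per KO) the same dual-mode tests
apply to KO abundances, either pooled or per (KO, species). Pathways pass
to gene-level follow-up when their FDR-adjusted p is below 0.1 in at
least **two of the six comparisons** (3 strata × 2 tests) — the only
reading that yields six comparisons from the strata and tests available —
and, for candidates, the per-species count of significantly *positively*
correlated member KOs summarizes which organisms carry the
odor-associated enzymes.

Community-level structure is assessed by canonical analysis of principal
coordinates (CAP) on Bray–Curtis dissimilarities, constrained on odor
intensity (numeric), age group, sampling time and sex (indicators).

## The synthetic cohort generator

No raw sequencing data accompany the workflow, so the generator is a
first-class module: every downstream stage is validated against cohorts
whose ground truth is known. It emulates:

* the **design**: 15 children + 15 teenagers, 8 female / 7 male in each
  group, 3 sites × 2 timepoints → 180 samples (the default enumerates this
  exactly; smaller designs scale the sex split proportionally);
* the **phenotype**: odor = site/group/timepoint baseline + subject random
  effect + planted-taxon contributions + noise, rounded to 0.1 and clipped
  to [0, 100]. Default baselines rise after exercise at every site, are
  higher in teens, and are highest at the underarm; subject and residual
  s.d. are 6 score units each. The variance of scores around group means
  is not something the source literature reports, so these defaults were
  chosen once for realistic-looking score spreads and adequate test power,
  and are not revisited;
* the **composition**: species relative abundances follow a
  logistic-normal model (log-scale s.d. 1.0) over 40 species, closed to
  100%, with a detection floor (default 0.001%) below which abundances are
  zeroed and the composition reclosed, emulating profiler sparsity.
  Planted species receive a high log-mean (2.2 vs. N(0, 1.5) for nulls),
  placing them near the top of the rank-abundance curve like the dominant
  staphylococci and cutibacteria of real skin;
* the **effects**: each planted effect ties one species, at one site and
  in one stratum, to the phenotype through a Gaussian copula. Within the
  effect's applicable samples the species' latent normal is
  `r* × (normal scores of the realized odor ranks) + sqrt(1 − r*²) × noise`
  with `r* = 2 sin(π ρ_target / 6)`, the classical latent-Pearson /
  Spearman conversion. Coupling to the *realized pooled ranks* (rather
  than to a shared factor alone) makes the copula immune to the baseline
  structure across timepoints and groups; a Monte-Carlo calibration run
  (100 replicates at defaults) shows mean realized ρ within ±0.03 of
  target for every default effect, and 96% of replicates within ±0.2 for
  a ρ = 0.8 effect at n = 30. An `exercise_shift` multiplier on the 8 h
  latent abundance plants the longitudinal signal;
* the **functional tables**: each species carries a fixed binary KO
  repertoire (default carriage 0.15 — specialized odor enzymes are
  sparsely distributed — with planted linked KOs always carried).
  Stratified RPK = species relative abundance × per-(family, species) copy
  factor × log-normal noise (s.d. 0.3); linked KOs of planted species use
  a fixed copy factor (8) so the planted functional signal is controlled
  rather than noise-dominated, while other pairs draw log-normal copy
  factors. An `unclassified` stratum takes a configurable fraction
  (default 10%) of each family's total, and community rows are exact sums
  of their strata. Pathway coverage is the fraction of member KOs with
  nonzero community abundance per sample; pathway abundance the sum of
  member-KO totals.

The default planted effects encode the qualitative association structure
this field reports: positive underarm effects for *S. epidermidis*
(carrying branched-chain amino acid degradation and pyruvate-metabolism
KOs — the isovaleric/acetic acid routes) and *C. avidum*; a
child-specific positive neck effect for *S. hominis* carrying
sulfur-catabolism KOs; negative neck effects for *A. schindleri* and
*C. acnes*. Magnitudes (|ρ| 0.45–0.6) sit in the reported range.

When several strong effects stack on one (site, group), the odor-side
contribution weights are jointly shrunk so that planted contributions
never demand more variance than the phenotype has; the abundance-side
copula is unaffected, so targets are still met. This is what makes
deliberately contradictory fixtures (two species at ±0.8 on the same
samples) well-defined.

Odor-character flags (sour, sulfur, greasy) are thresholded latent scores
driven by the positive planted contributions plus noise. They enable
character-distribution summaries; no chemical realism is claimed.

### What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis assumes
— monotone taxon–phenotype coupling, paired shifts, compositional
closure, stratified additivity, sparse repertoires — not read-level
reality: no sequences, no profiler biases beyond a detection floor, no
phylogenetic correlation among species, log-normal (not count) noise.
Tests passing on these cohorts validate the *pipeline's logic and error
control*, not any biological claim about real skin. One realistic
nuisance is present and worth knowing about: because abundances are
compositional, a strongly odor-coupled dominant species induces weak
*negative* correlations in the remaining species (shared denominator).
Error-control checks therefore run on all-null cohorts, where the nominal
behavior is exact; in planted cohorts an occasional null species near the
significance boundary is expected and realistic.

## Numerical and inferential choices

* **Spearman p-values**: exact (full permutation null) for n ≤ 9 without
  ties, t-approximation otherwise. Exactness at small n is
  oracle-checkable by complete enumeration.
* **Signed-rank**: zero differences dropped (classic Wilcoxon); exact via
  the signed-rank distribution for ≤ 25 untied nonzero pairs; for tied
  samples with ≤ 12 nonzero pairs, exact by enumerating all 2^n sign
  assignments on midranks; otherwise a tie-corrected normal approximation
  with continuity correction. All differences zero is a degenerate
  outcome (p = 1, direction none), not an error.
* **Rank-sum**: exact for small untied samples; exact by enumeration over
  group assignments for small tied samples; tie-corrected normal
  approximation otherwise.
* **Two-sided convention**: symmetric tail mass around the null mean,
  which coincides with twice the smaller tail for the symmetric untied
  null distributions.
* **BH adjustment**: standard step-up, order-equivariant, capped at 1.
* **Degenerate features**: a feature constant across a stratum's samples
  is excluded from that family with a logged reason — a batch should not
  die because the detection floor flattened one rare species.
* **Strict inequalities** in every abundance gate (taxa > 1% mean in
  either age group, per site; gene families > 10 mean community RPK in
  either group; pathways > 0.3 mean coverage across all the site's
  samples). Gene-family renormalization divides each sample by the sum of
  *surviving community rows*, scaling all strata by the same factor —
  per-sample renormalization is the choice that keeps downstream
  correlations on relative abundances, and it preserves stratified
  additivity exactly.
* **CAP**: realized as distance-based RDA — PCoA of the Bray–Curtis
  matrix, regression of the positive-eigenvalue axes on the constraints,
  eigen-analysis of the fitted values (vegan's `capscale`). Negative
  eigenvalues are reported, not corrected. The permutation p is
  `(1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` under row permutation of the
  constraints (default 999 permutations, so the p floor is 0.001),
  deterministic given the seed. Which CAP variant (discriminant CAP vs.
  distance-based RDA) underlies published figures of this kind is rarely
  stated; both give the same qualitative permutation test, and the
  distance-based RDA variant decomposes inertia additively
  (constrained + unconstrained = total over positive axes, a tested
  identity).
* **Seeds**: a single integer master seed; each stage (cohort, taxa,
  genes, ordination) derives a child stream by a fixed labelled offset, so
  stages are independently reproducible and an extra draw in one stage
  cannot perturb another. All derived seeds stay below 2^31.

## Problem sizes used by the test suite

The suite validates the engines against complete-enumeration oracles at
n ≤ 8 (200 randomized cases across the three tests), calibrates recovery
on 100 single-site cohorts of 30 samples × 21 species, measures
false-flag rates on 100 all-null cohorts, and checks CAP null-p
uniformity on 200 cohorts of 32 samples × 12 species at 99 permutations.
These sizes give stable Monte-Carlo estimates (binomial s.e. ≈ 3% on
recovery rates) while keeping a full run in the minutes range on one
core.

## Known limitations

* Repeated measures enter the cross-sectional test as independent
  samples; a mixed-effects extension is out of scope by design.
* The compositional induced-correlation effect described above means
  FDR statements on planted cohorts are approximate at dominant planted
  shares; they are exact on null cohorts.
* The bundled KO catalog is a deliberately small synthetic stand-in
  (five pathways, 33 KOs); real KEGG mappings can be supplied as
  two-column tables wherever a `ko_map` is accepted.
* Pathway-level community associations are intentionally marginal at the
  default settings: summing a pathway over all carriers dilutes a
  single species' signal — which is precisely the bag-of-genes weakness
  the stratified mode exists to expose.
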
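---
title: "Methods: differential regulation of membrane lipidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential regulation of membrane lipidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcontrast)
```

# The analysis model

`lipidcontrast` analyses species-level shotgun-lipidomics concentration
tables (lipids × samples, pmol) from comparative designs: cancer cell
lines against a healthy control, each optionally probed with a pathway
perturbation, with a small number of biological replicates per condition
(three in the motivating design). The pipeline is deliberately simple and
auditable; every rule below is encoded exactly once and covered by tests.

## Missingness

Shotgun lipidomics reports no value when a species falls below the
detection limit in a sample. Such cells are *missing*, not zero: they are
excluded from normalization denominators, means and tests, and a measured
zero is kept distinct from a missing cell. No imputation is performed
anywhere. Upstream of concentrations, intensity-level data can be screened
with the acquisition filter: a cell is kept only if its signal-to-noise
ratio is strictly greater than `snr_min` (default 5) and its signal is
strictly greater than `blank_fold_min` (default 5) times the corresponding
blank-sample intensity; cells failing either strict inequality become
missing. Delivered pmol tables are assumed to be already filtered, so the
filter is exposed for intensity inputs and synthetic data only.

## Normalization

Absolute amounts depend on the quantity of material infused, so all
inference runs on relative abundance: each present value is divided by the
sum of the present values of the same sample and multiplied by 100
("mol%"). Every non-degenerate sample then sums to exactly 100; the
operation is idempotent and invariant to rescaling any single sample's raw
vector. A sample with no positive present value is refused by name rather
than silently propagated.

## Contrasts and DRL calls

For a contrast of a test group over a reference group (cancer line over
control, or treated over untreated of the same line), each lipid gets

* `log2fc` — the log2 ratio of the group means, computed over present
  replicate mol% values only (ratio of means, not mean of ratios);
* `p_value` — a two-tailed two-sample Student's *t*-test on the
  per-replicate mol% values, classical pooled-variance by default
  (`equal_variance = TRUE`); the Welch variant is available because the
  equal-variance assumption is questionable with three replicates, but the
  pooled test is the default for fidelity to the standard workflow.

A lipid is considered only when both groups have at least
`min_replicates = 2` present replicates; otherwise it is excluded from the
contrast output (with a logged reason), which downstream stages treat as
*not evaluable* — deliberately distinct from "tested and non-significant".
A group mean of exactly zero also excludes the lipid, since its log2 fold
change is undefined. A lipid is a differentially regulated lipid (DRL)
when `p_value < alpha` (default 0.05, raw), with direction Up or Down from
the sign of `log2fc`. No multiple-testing correction is applied by
default, matching the raw-threshold convention of the motivating workflow;
`p_adjust = "BH"` (or any `stats::p.adjust` method) is available and is an
explicit deviation recorded in the result parameters.

Numerical conventions for degenerate inputs: when both groups have zero
variance, equal means give *t* = 0, *p* = 1 and unequal means give
*t* = ±Inf, *p* = 0. "Equal" is assessed within a relative tolerance of
1e-8, so group means that differ only by floating-point accumulation
(inevitable after compositional normalization) are not declared different.

## Interaction taxonomy

Per cell line, the cancer contrast and the treatment contrast combine into
five mutually exclusive, exhaustive categories driven entirely by the
significance-gated directions:

| cancer | treatment | category |
|---|---|---|
| Up/Down | opposite | moderates |
| Up/Down | same | amplifies |
| Up/Down | none | no_treatment_effect |
| none | Up/Down | side_effect |
| none | none | unaffected |

A lipid excluded from one contrast by the replicate rule has direction
`none` there but carries a `not_evaluable_*` flag, and per-category counts
are reported both inclusively and strictly (dropping not-evaluable
lipids), so absence of evidence is never silently converted into evidence
of absence. Directional DRL sets from several contrasts are compared with
exact-combination (upset-semantics) counts; concordant mode counts a
shared lipid toward Up/Down only when its direction agrees in every set
containing it, and reports disagreements as discordant.

## Multivariate views

Fold-change profiles are clustered on the lipids-by-contrasts matrix in
which a cell carries the lipid's log2 fold change when it is a DRL in that
contrast and 0 otherwise (the zero-fill rule); a mask records whether each
zero is a genuine fill of a missing or of a non-significant effect, and
filling never alters a significant cell. Distance is 1 − Pearson *r* with
average linkage — the linkage is not dictated by the workflow being
reproduced, so the common heatmap default was chosen and is exposed as a
parameter. A zero-variance profile has undefined correlation; by
convention it sits at distance 1 (uncorrelated) from everything and is
reported. PCA runs on column-centered mol% profiles without unit-variance
scaling (mol% values share a scale; scaling is available as a flag), drops
lipids with any missing value (reported), and fixes each component's sign
by making the largest-magnitude loading positive, so results are
reproducible across platforms and sample orders.

# The synthetic generator

The generator emulates the statistical structure of a delivered shotgun
lipidomics study so that every stage has ground truth:

* **Composition** — species names are drawn from the shorthand grammar,
  by default ~274 species over 21 classes in realistic proportions
  (PC/PE-dominated, with sphingolipids carrying a di-hydroxylated
  long-chain base).
* **Abundance** — baseline log10 pmol ~ Normal(2, 0.6), i.e. a median of
  100 pmol spanning roughly 1–10,000 pmol, the typical dynamic range of
  direct-infusion quantification.
* **Replicates** — multiplicative lognormal noise with a configurable
  coefficient of variation (default 10%, a realistic biological-replicate
  spread; 0 gives exactly reproducible values), mean-preserving.
* **Censoring** — values below `detection_limit_pmol` (default 10, which
  yields roughly 5–15% missingness under the defaults) become missing and
  are flagged in the truth.
* **Effects** — per cell line, each lipid receives one of the five
  interaction categories with *exact* counts (largest-remainder
  apportionment of the configured mix, default uniform), which determines
  the signs of its planted cancer and treatment log2 fold changes of
  magnitude `effect_log2fc_magnitude` (default 2). One global seed governs
  everything; identical seeds give bitwise-identical tables.

**Mass balance.** A plasma membrane's total lipid content is, to first
order, fixed: regulation shifts composition, not amount. The generator
therefore constrains planted multipliers so that each condition's total
pmol equals the control total. Without this constraint the mol%
denominator would shift by a common factor and every unaffected species
would acquire a spurious, fully significant apparent fold change — an
artefact of simulating unconstrained effects, not a property of the
analysis. Directions are assigned by greedy two-dimensional balancing of
each lipid's contribution to the untreated and treated condition totals
(descending baseline order), and the residuals are closed exactly by
adjusting the *magnitude* — never the sign, hence never the category — of
the largest-baseline moderated lipid and side-effect lipid per line. Two
consequences are documented rather than hidden: Up/Down assignments are
mass-balanced rather than independent coin flips (down-regulation is more
frequent, since a 4-fold increase needs four 0.25-fold decreases of equal
mass to balance), and two lipids per line carry a slightly off-nominal
magnitude, recorded as such in the truth table.

**What the generator does not emulate:** class-correlated abundances,
batch or acquisition-order drift, adduct/isotope interference,
heteroscedasticity beyond the single CV, or correlated replicate noise.
Passing recovery tests therefore demonstrates that the statistical
machinery is correct under the stated model, not that real data meet that
model.

# Verification scale and observed behaviour

The test suite and the acceptance script compute (not assert from
constants): a type-I error of ≈0.05 for the DRL call on 10,000 null lipids
(two groups × three replicates, 10% CV lognormal noise); *t* statistics
and *p*-values within 1e-10 of `stats::t.test` on 100 random fixtures;
average-linkage merge heights and upset counts equal to brute-force
oracles on small fixtures; ≥90% interaction-label recovery at planted
|log2fc| = 2, 10% CV, five replicates, 500 lipids evenly split over the
five categories (observed ≈96–97%), and exact recovery on noise-free
data; mol% conservation to 1e-9; antisymmetry of contrasts under group
swap; and exact parse/render round-trips on 1,000 grammar-random names
plus the 19-standard spiked mixture. Recovery experiments run without
detection-limit censoring so that they measure the classifier, not the
censoring process; censoring behaviour is tested separately (monotonicity
in the limit, total-censoring degeneracy, filter interplay). These problem
sizes keep the whole suite under a minute on one core while leaving
binomial noise well inside the asserted margins.

# Known limitations

* The *t*-test with *n* = 3 has limited power and fragile variance
  estimates; the pipeline reproduces that convention rather than improving
  on it (no moderated/shrinkage variance).
* Raw *P* < 0.05 across hundreds of lipids implies a non-trivial
  false-discovery rate; the BH option exists but changes the DRL
  definition.
* mol% data are compositional; fold changes are interpretable relative to
  the whole measured lipidome, and a strong change in an abundant class
  necessarily perturbs the apparent abundance of others. The interaction
  taxonomy inherits the significance gate: with low power, "none" conflates
  "no effect" with "undetected effect", which is why not-evaluable flags
  and strict counts are reported.
* Sample metadata accepts any treatment label (with `"none"` reserved for
  untreated) rather than a fixed vocabulary, so the pipeline extends to
  other perturbations; the motivating design's labels (Wnt3a, Dkk1) are
  defaults in the generator only.
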
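# lipidcontrast

Differential-regulation analysis for species-level shotgun lipidomics.

Plasma-membrane lipidomes are quantified by direct-infusion mass
spectrometry as pmol amounts of individual lipid species ("PC 16:0/18:1",
"Cer 18:1;2/24:0", ...). A typical comparative design — hepatocellular
carcinoma (HCC) cell lines against a healthy control line, with and without
a perturbation such as Wnt3a or Dkk1 treatment — asks three questions:
which species are differentially regulated in cancer, which respond to the
treatment, and how the two effects interact. `lipidcontrast` implements
that analysis as a tested, reusable pipeline:

* **Nomenclature** — a parser for Lipotype-style shorthand names that
  assigns every species to one of 23 lipid classes and 5 categories
  (sterols, sphingolipids, glycerolipids, glycerophospholipids,
  glycerophospholipid intermediates), with exact parse/render round-trips.
* **Ingest** — delimited-text concentration matrices with explicit
  below-detection-limit missingness (never imputed), the acquisition-stage
  identification filters (signal-to-noise ratio strictly greater than 5 and
  signal strictly greater than fivefold the blank intensity), and mol%
  normalization: each present value divided by its sample's present-value
  sum, times 100.
* **Differential regulation** — per lipid, the log2 fold change of group
  means over present mol% replicates and a two-tailed Student's *t*-test;
  a lipid is a differentially regulated lipid (DRL) when *P* < 0.05
  (raw; Benjamini–Hochberg is an opt-in deviation), with direction Up or
  Down from the sign of the fold change. Missing replicates are neglected,
  and a lipid is considered only with at least two present replicates in
  both conditions.
* **Interaction taxonomy** — per lipid and cell line, the cancer contrast
  (cancer vs. control) and the treatment contrast (treated vs. untreated)
  combine into five mutually exclusive categories: treatment *moderates*
  the cancer effect (directions reversed), *amplifies* it (same
  direction), *no treatment effect*, *side effect* of treatment
  (treatment-only change), or *unaffected*. Directional DRL set overlaps
  (upset-style exact-combination counts, with concordant Up/Down splits)
  compare cell lines.
* **Multivariate views** — lipids-by-contrasts log2 fold-change matrices
  with the zero-fill rule (missing and non-significant effects are set to
  0, with a provenance mask), agglomerative clustering on 1 − Pearson *r*
  with average linkage, and column-centered PCA of mol% profiles with a
  fixed sign convention.
* **Synthetic data** — a fully seeded generator producing Lipotype-like
  pmol tables with lognormal abundances, multiplicative replicate noise,
  detection-limit censoring, and planted, mass-balanced cancer/treatment
  effects with known interaction labels, so every stage is testable
  without external data.

## Worked example

```r
library(lipidcontrast)

parse_species("Cer 18:1;2/17:0")
#> <lipid_species> Cer 18:1;2/17:0 [Cer, sphingolipids]

# A study-shaped synthetic dataset: control line THLE2 plus three HCC
# lines, n = 3 replicates, Wnt3a treatment, known planted truth.
sim <- generate_dataset(sim_config(seed = 2026))
sim$table
#> <conc_table> 274 lipids x 21 samples [pmol], 943 missing cells
#>   cell lines: THLE2, HUH7, SNU475, Hep3B

tab    <- normalize_mol_pct(sim$table)
cancer <- compute_contrast(tab, c("THLE2", "none"), c("Hep3B", "none"))
wnt    <- compute_contrast(tab, c("Hep3B", "none"), c("Hep3B", "Wnt3a"))

head(drl_table(cancer)[, c("lipid", "lipid_class", "log2fc", "p_value",
                           "direction")], 3)
#>     lipid lipid_class    log2fc      p_value direction
#> 1 CE 12:1          CE -2.061989 3.923100e-05      Down
#> 2 CE 14:1          CE -2.106088 9.594252e-06      Down
#> 3 CE 16:3          CE  2.097685 1.140196e-04        Up

calls <- classify_interaction(cancer, wnt)
interaction_counts(calls)
#>           moderates           amplifies no_treatment_effect
#>                  48                  18                  69
#>         side_effect          unaffected
#>                  49                  49
```

The DRL table shows, per species, the log2 fold change of the Hep3B mean
mol% over the control mean and the *t*-test *P*-value; `interaction_counts`
summarizes how Wnt3a treatment interacts with the cancer effect across the
233 lipids evaluable in at least one contrast. Because the data are
synthetic, the calls can be checked against the planted truth:

```r
truth <- subset(sim$truth$effects, cell_line == "Hep3B")
mean(as.character(calls$interaction) ==
       truth$category[match(calls$lipid, truth$lipid)])
#> [1] 0.8497854

pca_molpct(tab, n_components = 2)
#> <lipid_pca> 21 samples, 2 components (50.1/17.8% variance)
#>   128 lipids dropped for missing values
```

About 85% of planted labels are recovered under this deliberately hard
design (three replicates, 10% replicate CV, 10 pmol detection limit);
with five replicates and no censoring recovery exceeds 95%, and it is
exact on noise-free data (see the methods vignette).

A thin command-line wrapper over the same functions is shipped at
`inst/cli/lipidcontrast.R` with `simulate`, `contrast`, `classify` and
`report` subcommands.

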
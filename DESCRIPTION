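Package: lipidcontrast
Title: Differential Regulation Analysis of Shotgun Lipidomics Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for species-level shotgun lipidomics
    concentration matrices: parsing of lipid shorthand nomenclature with
    class and category annotation, acquisition-stage signal-to-noise and
    blank filtering, mol percent normalization with explicit
    detection-limit missingness, per-lipid two-group contrasts with
    replicate-count rules and differential-regulation calls, a five-way
    cancer-by-treatment interaction taxonomy with directional set-overlap
    summaries, Pearson-correlation clustering of zero-filled log2
    fold-change profiles, principal component analysis of mol percent
    profiles, and a fully seeded synthetic data generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
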
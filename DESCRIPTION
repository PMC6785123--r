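Package: pathlight
Title: Light and Dark Pathway Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies biological pathways statistically enriched for somatic
    mutations or copy-number alterations in a tumor cohort using hypergeometric
    over-representation with Benjamini-Yekutieli false-discovery-rate control,
    classifies each enriched pathway as drug-targetable ("light") or untargeted
    ("dark") against a tiered drug-target evidence table, and prioritizes
    pathways by pathway pathogenicity and cohort coverage. Includes HPV-status
    stratification with confidence tiers, pathway-hierarchy nesting annotation
    (dark pathways nested under light ancestors), readers for MAF-like mutation
    tables, GISTIC-thresholded copy-number matrices, GMT/TSV pathway databases
    and drug-target tables, and a seeded synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
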
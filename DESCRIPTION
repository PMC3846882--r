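Package: apmsref
Title: Prey Scoring and Relative Enrichment Analysis for AP-MS Protein
    Complex Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for affinity purification-mass spectrometry
    (AP-MS) spectral count data: identification filtering, NSAF (normalized
    spectral abundance factor) profiles, probabilistic bait-prey interaction
    scoring against mock controls with replicate averaging, relative
    enrichment factors (REF) against a known core-complex reference set,
    in-silico tryptic digestion with isoform-unique peptide classification,
    and a seeded synthetic-data generator that plants a recoverable complex
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
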
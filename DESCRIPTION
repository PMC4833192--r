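Package: idpanel
Title: Proband-Only Gene-Panel Variant Triage and Carrier-Burden Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnostic analysis of targeted gene-panel sequencing in
    proband-only cohorts, as used for intellectual disability panels:
    rare-variant frequency filtering against reference populations,
    inheritance-aware triage of loss-of-function and known pathogenic
    missense variants into likely-pathogenic, uncertain or excluded
    verdicts with machine-readable reason codes, stratified
    carrier-enrichment testing against a comparison cohort with the
    cohort allelic sums test (CAST), and a synthetic case-control cohort
    generator with full ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
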
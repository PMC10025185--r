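Package: toxtriage
Title: Confidence-Stratified In Silico Hazard Triage for Industrial Chemicals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale triage pipeline for the regulatory hazard profiling
    of industrial chemical inventories. Substance registries keyed on CAS
    Registry Numbers are curated structurally (organic / salt / organometallic
    / inorganic / peptide categorisation with desalting), multi-source hazard
    annotations (ECHA CLP/REACH/SVHC, registration dossiers, reference
    databases, Pharos) are integrated into per-endpoint labels for CMR,
    endocrine disruption, PBT and vPvB, and annotation gaps are filled with
    Mondrian inductive conformal random-forest classifiers (per-class
    p-values, significance and confidence reporting, balanced-subset majority
    voting) and Tanimoto fingerprint read-across. Includes confidence-
    stratified gap-filling accounting, prospective validation candidate
    selection, and deterministic synthetic-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
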
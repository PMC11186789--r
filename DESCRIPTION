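Package: medic
Title: Medication Direction Standardization, Extraction and Safety Guardrails
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline that converts raw prescriber medication directions
    (sigs) into standardized, patient-safe directions. It normalizes noisy
    sig text with an ordered rule engine, extracts nine direction components
    (verb, dose, route, frequency and five auxiliary sub-entities) with
    either a deterministic dictionary tagger or a trainable sequence tagger,
    assembles the components in canonical order under a medication catalog
    and five ordered safety guardrails, and flags semantic discrepancies
    between two directions by component-wise comparison. Includes a corpus
    factory that builds component and pattern libraries from labeled data
    and generates synthetic labeled corpora for training and evaluation,
    plus BLEU/METEOR scoring of generated directions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
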
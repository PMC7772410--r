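Package: operomer
Title: Evidence-Integrated Functional Annotation of Hypothetical Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Functional annotation workflow for the uncharacterized fraction
    of a prokaryotic proteome (the "operome"). Integrates prediction evidence
    from six channels (motif, domain, structure, evolutionary trace,
    physicochemical, localization) with literature provenance graded on a
    six-level taxonomic scale into a twelve-level confidence score with
    retention rules; computes sequence-derived physicochemical properties
    (molecular weight, theoretical pI, instability index, aliphatic index,
    GRAVY); calls transmembrane segments by sliding-window hydropathy;
    assigns retained proteins to functional categories and metabolic
    subsystems; and detects operon-like gene clusters from genome layout.
    Ships curated annotation tables for the Methanobrevibacter ruminantium
    M1 operome and a seeded synthetic-data generator so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
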
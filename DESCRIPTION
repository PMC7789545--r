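Package: rwegm
Title: Mining Real-World Evidence of Genetic Testing from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for generating real-world evidence about the clinical
    utility of genetic tests from unstructured clinical notes. Extracts
    gene-mentioning sentences (BRCA1/2 by default), masks gene and
    HGVS-style variant mentions, scores sentence universality with
    sf-ipf (sentence frequency times inverse patient frequency),
    discovers topic-indicating words by pointwise mutual information,
    classifies sentences into seven clinical-context topics with both a
    rule-based system and a bagged randomized-tree classifier, curates
    variant assertions into a clinical-genomics data model, audits field
    completeness and documentation discrepancies against reference
    reports, builds patient topic timelines, and tests the association
    between mutation status and targeted-therapy discussion or
    prescription with an exact conditional test for r x c contingency
    tables. Includes a synthetic-cohort generator providing gold labels
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    stringi
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
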
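Package: gesreversal
Title: Signed Jaccard Similarity Analysis of Drug and Disease Gene
    Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Evaluates gene expression signature (GES) guided drug-disease
    association. Reads CREEDS-style collections of up/down differential
    expression signatures, applies the human/FDA-approval/dual-label
    inclusion protocol, scores every drug-disease signature pair with the
    signed Jaccard index, aggregates to unique drug-disease pairs labelled
    by FDA indication, tests indicated-vs-control mean differences overall
    and within annotation subgroups (ICD-11 disease class, drug target
    subfamily, transcription-factor level, chemotherapy status, ATC level
    3) via least-squares-means slice F tests with Benjamini-Hochberg FDR,
    and ranks genes by the relative reversal score G^I-R%. Ships a
    synthetic study generator with planted reversal structure for
    end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
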
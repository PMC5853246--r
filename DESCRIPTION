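Package: cacaoSI
Title: Genetics of Late-Acting Self-Incompatibility in Theobroma cacao
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the genetic analysis of the two-locus late-acting
    self-incompatibility (LSI) system of cacao. Provides an executable
    formalization of the S-allele dominance model with a pre-fusion
    zygotic-elimination locus and a gamete-fusion-failure locus, a forward
    simulator of selfings, crosses and mentor-pollen mixed pollinations, a
    segregation-distortion scanner that delimits candidate incompatibility
    regions from progeny marker tables, a diagnostic SSR-marker screening
    procedure (exact tests with FDR control, conditional and dose-response
    probabilities of self-compatibility), allele-frequency and
    variety-specific-allele reports by genetic group, relative qPCR
    expression quantification, and synthetic-data generators that emulate
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
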
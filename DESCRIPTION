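Package: dcscreen
Title: Disease-Specific Drug-Combination Screening from Transcriptomic,
    Network and Dose-Response Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate partner compounds for reference drugs by
    transcriptional orthogonality to the reference and reversal of a disease
    expression signature (concordance ratio, disease discordance ratio and
    orthogonality score computed from signed consensus signatures), assesses
    candidate pairs on a protein-protein interaction network via
    degree-matched network proximity z-scores and module separation
    ("Complementary Exposure" classification), and scores dose-matrix
    viability data with Bliss and ZIP reference models including the most
    synergistic area. Ships seeded synthetic-data generators with planted
    ground truth for every pipeline input so the whole screen is testable
    without external datasets.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
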
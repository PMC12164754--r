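Package: ribopause
Title: Codon-Resolution Ribosome Profiling and Translational Repression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for quantifying translational repression from
    ribosome profiling, RNA-seq, polysome profiles and metabolite tables in a
    wild-type versus mutant comparison. Implements P-site offset inference from
    start-codon metagenes, reading-frame filtering, per-codon A/P/E-site pausing
    scores, negative-binomial interaction tests for differential translation
    efficiency, nine-quadrant transcriptome/translatome classification,
    polysome-to-monosome ratio quantification, and a PLS-DA VIP plus fold-change
    metabolite screen. Ships a synthetic-data generator with recorded ground
    truth (codon dwell multipliers, TE effects, peak areas, differential
    metabolite flags) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    Rsamtools,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
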
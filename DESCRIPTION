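Package: aluscape
Title: Alu Element-Based Genomic Instability Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Scores the relative deletion instability of human genes and
    coding exons from the Alu retroelement landscapes that surround them.
    Calibrates genome-wide inverted-to-direct (I:D) Alu pair ratio surfaces
    over spacer size, Alu pair sequence number (APSN) and clustering type
    from RepeatMasker-style annotations; combines the fitted surface with a
    hybrid deletion-size probability distribution to obtain per-Alu end
    stabilities, iScores, and survival-product stabilities for exons and
    genes. Includes a seeded synthetic-landscape simulator with controlled
    inverted-pair thinning for calibration parameter-recovery experiments,
    and a command-line interface for calibrate/score/sensitivity/simulate
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
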
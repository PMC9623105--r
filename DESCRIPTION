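Package: racketpcr
Title: Primer Design and In Silico Simulation of Fusion Primer-Driven
    Racket PCR Genome Walking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs walking-primer sets for fusion primer-driven racket
    PCR (FPR-PCR), a genome-walking method that retrieves unknown DNA
    flanking a known region, and simulates the two-round amplification in
    silico.  A designer enumerates the four sequence-specific fragments
    (SSP1, SSP2, SSP3/FISA, SSP4) from a known sequence under length, Tm
    and self-structure constraints and assembles the FISA+SSP1 fusion
    primers.  A strand-pool simulator models the three-stage primary
    reaction (stringent SSP1-part priming, one mismatch-tolerant
    low-stringency cycle, exponential full-primer cycles with
    intra-strand loop-back forming racket-like DNA) and the secondary
    end-to-end PCR, predicting amplicons, recovered flank sequence and
    walk distance.  A seeded fixture generator plants partial-annealing
    sites in synthetic genomes so every prediction is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
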
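Package: lactylmine
Title: Mining and Validation of Lysine Lactylation Sites from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for mining lysine-lactylated peptides
    from centroided MS/MS data: in-silico tryptic digestion, peptide-spectrum
    matching with target-decoy false discovery rate control, AScore site
    localization, validation by the cyclic immonium (CycIm) diagnostic ion of
    lactyllysine, cohort-level site summaries (detection frequency, intensity
    rank, modification occupancy), and cross-species conservation assessment by
    Poisson-corrected Neighbor-Joining phylogenetics with bootstrap supports.
    Includes a synthetic-data generator that simulates spectra and multi-sample
    cohorts with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
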
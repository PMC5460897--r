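Package: chargescape
Title: Proteome-Wide Protein Charge Distribution and Its Impact on Translation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to profile the electrostatic landscape of proteomes and relate it
    to translation. Computes per-residue ionization charges at a chosen pH from a
    Henderson-Hasselbalch residue model, scans every 30-residue segment of each
    protein for its net charge (the length of nascent peptide held in the ribosome
    exit tunnel), and summarises the resulting charge landscape: sign fractions,
    negative/positive ratio curves, positional charge averages, N/core/C-terminal
    heat-map matrices, and detection of supercharged stretches. Downstream modules
    analyse ribosome-profiling per-codon read counts (coverage filtering, per-gene
    normalization, metagene occupancy curves by N-terminal charge group, area-under-
    curve ratios) and stratify genes across monosome/polysome translation classes.
    A synthetic-data generator produces proteomes, ribosome count profiles and
    monosome:polysome scores with known planted structure so that every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    pracma,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
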
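Package: pkvtools
Title: Phylogenetic Kinetic Value Conservation Spectra for Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-column conservation analysis of protein multiple sequence
    alignments built around the phylogenetic kinetic value (PKV), a
    second-moment statistic of the rank-abundance spectrum of residues at
    each alignment column, alongside classical Shannon information entropy.
    Includes aligned-FASTA import, column censusing, mapping of alignment
    columns to ungapped reference-sequence numbering, conserved-region
    calling, import of external per-residue score tracks, sliding-window
    hydropathy profiles, point-mutagenesis helpers, average molecular
    weight calculation, and a seeded synthetic-alignment generator with
    planted conserved blocks for benchmarking recovery of conserved motifs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
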
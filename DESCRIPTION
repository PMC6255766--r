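Package: mitocomp
Title: Comparative Analysis of Vertebrate Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes: gene-table metrics (lengths, overlaps,
    intergenic spacers, start/stop codon classification), nucleotide
    composition and AT/GC strand skew by genome partition, relative
    synonymous codon usage under the vertebrate mitochondrial code,
    constrained cloverleaf folding and base-pair classification for
    tRNA genes, tandem-repeat, motif and stem-loop detection in the
    control region, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction, Kimura two-parameter distances and
    neighbor-joining trees on concatenated protein-coding genes, and a
    synthetic mitogenome generator with full truth records for
    validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
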
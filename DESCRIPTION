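Package: duimito
Title: Comparative Analysis of Gender-Associated (DUI) Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the maternally (F) and paternally (M)
    inherited mitochondrial genomes of bivalves with doubly uniparental
    inheritance (DUI). Parses annotated mitogenomes (GenBank flat file,
    FASTA plus feature table) into a circular genome model and computes
    architecture statistics (overlaps, unassigned regions, start/stop codon
    classes, ORF scans, the male cox2 extension), strand-asymmetry AT/GC
    skews and per-partition base composition, codon usage with RSCU,
    amino-acid-guided codon alignment with p-distances, site-bootstrap
    standard errors and Nei-Gojobori (NG86) Ka/Ks with Jukes-Cantor
    correction, Fickett TESTCODE coding-potential scores, tandem-repeat and
    stem-loop based control-region detection, signed circular gene-order
    comparison (breakpoint distances, clade-diagnostic adjacencies), and a
    light neighbor-joining surface for reciprocal-monophyly checks. A
    deterministic synthetic-genome generator provides a download-free test
    surface emulating unionoid F/M mitogenome pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
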
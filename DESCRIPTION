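Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of insects, with an emphasis
    on the rearrangement-prone genomes of parasitoid wasps. Reads annotated
    mitochondrial genomes from GenBank flat files, computes strand
    compositional asymmetry (AT and GC skew) and calls reversal of strand
    asymmetry, extracts signed circular gene orders and classifies
    rearrangement events (shuffling, local inversion, translocation, remote
    inversion) against the ancestral hexapod arrangement, detects pseudogene
    remnants in intergenic spacers, annotates the structural elements of the
    A+T-rich (control) region and infers its orientation, estimates Ka, Ks
    and Ka/Ks by the Nei-Gojobori method with Jukes-Cantor correction, and
    builds codon-partitioned phylogenetic supermatrices (amino acid, Pos12,
    Pos123, Pos12RY3) in ancestral gene order. A deterministic synthetic
    mitogenome generator with ground-truth event logs supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
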
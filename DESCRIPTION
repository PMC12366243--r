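Package: phosmine
Title: Gene-Context Mining and Kinetic Modeling of Bacterial Phosphonate Catabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-context analysis of the hydrolytic pathways for
    2-aminoethylphosphonate (AEP) degradation in bacteria: reading annotated
    genomes (GFF3 plus protein FASTA), global protein alignment with affine gap
    penalties and a shorter-sequence percent-identity statistic, marker-based
    role assignment, colocalization-based detection and typing of AEP-degradation
    gene clusters (phnWX and phnWYA cores with ancillary pbf genes), a nested
    census of phnA genomic neighborhoods stratified by taxonomic order, and a
    quantitative kinetics layer covering initial-rate extraction, Michaelis-
    Menten fitting of coupled racemase assays, and mass-action simulation of an
    NAD-dependent racemization mechanism. A synthetic-genome generator with
    ground-truth manifests makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
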
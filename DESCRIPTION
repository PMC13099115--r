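Package: ervmine
Title: Mining, Annotation, Dating and Comparative Analysis of Endogenous
    Retrovirus Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for characterizing endogenous retrovirus
    (ERV) insertions in host genome assemblies: native seed-and-extend
    homology mining of proviral loci, LTR-pair and target-site-duplication
    detection, gene and peptide annotation with ORF scanning, a five-class
    structural taxonomy of copies, insertion dating from LTR divergence
    under the Kimura two-parameter molecular clock (T = K/2r),
    triplet-based recombination screening (MaxChi, Chimaera, RDP-style
    window scan) with a consensus removal rule, cross-genome orthologous
    locus matching with Fisher exact count comparisons, and distance-based
    (neighbor-joining) phylogenetics with bootstrap support. Includes a
    provirus-evolution simulator that implants copies with target-site
    duplications, neutral LTR divergence, solo-LTR collapse, internal
    deletions and duplications, recombination and host-pedigree
    inheritance, emitting machine-readable ground truth so every stage is
    benchmarkable without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
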
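Package: dsbsig
Title: Infer DNA Double-Strand-Break Repair Mechanisms from Genome Assemblies
Version: 0.1.0
Authors@R: person("dsbsig", "developers", email = "dsbsig@example.org",
    role = c("aut", "cre"))
Description: Annotates the DNA double-strand-break (DSB) repair mechanism
    underlying non-repetitive insertions, deletions and complex substitutions
    called between a reference genome and a query genome assembly. Variant
    breakpoints are corrected by re-locating 2-kb flanking sequences in the
    query assembly, repetitive variants are removed with a built-in tandem
    repeat detector, micro/homology and templated-insertion signatures are
    detected at variant junctions, and polymerase theta-mediated end joining
    (TMEJ) is separated from single-strand annealing (SSA) by modelling the
    micro/homology length distribution as two box-constrained Poisson
    components split at a local-regression minimum. A deterministic synthetic
    genome generator with a mechanism-labelled truth table supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
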
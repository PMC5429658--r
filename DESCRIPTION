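Package: g4screen
Title: Screening Somatic 5' UTR Mutations for RNA G-Quadruplex Stability Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies somatic single-nucleotide variants that alter the
    predicted stability of RNA G-quadruplexes (G4s) in spliced 5' UTRs.
    Enumerates putative quadruplex loci with the Quadparser motif and a
    QGRS-style overlapping-candidate scorer, assembles strand-aware 5' UTR
    sequences from genome plus annotation, maps variants into transcript
    space, compares wild-type against mutant candidate decompositions to
    classify each variant as destabilising, stabilising or neutral with a
    mechanism label (tetrad loss/gain, loop lengthening/shortening, locus
    shift), and optionally corroborates calls with minimum-free-energy
    folding through a ViennaRNA adapter. Also provides the accompanying
    assay mathematics (circular-dichroism spectrum smoothing and molar
    ellipticity conversion, variable-slope sigmoidal melt-curve Tm fitting,
    Pfaffl efficiency-corrected expression ratios, relative translation
    efficiency) and a seeded synthetic-cohort generator that plants G4 loci
    and effect-class-labelled mutations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
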
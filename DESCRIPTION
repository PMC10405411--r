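Package: dicerscope
Title: Simulation and Detection of Plant Dicer Small RNA Signatures in
    RNAi-Depleted Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how a plant Dicer-like 4 (DCL4) endonuclease,
    expressed in the RNAi-depleted budding yeast Saccharomyces cerevisiae,
    leaves detectable signatures in small RNA sequencing data. The package
    simulates Dicer processing of inverted-repeat hairpin transcripts,
    replicase-protected viral replicons and sense/antisense co-transcribed
    loci into 20-22 nt small RNA duplexes with 2-nt 3' overhangs, generates
    sequencing-style reads with full ground-truth provenance, and detects
    the signatures back from reads: size-class profiling, Fisher-exact
    localization of the hairpin loop boundary, strand-symmetric antisense
    locus classification, and a negative-binomial Wald test for
    differential expression with median-of-ratios normalization and
    Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'align.R'
    'antisense.R'
    'dicer.R'
    'dicerscope-package.R'
    'diffexpr.R'
    'genome-srna.R'
    'hairpin-analysis.R'
    'io.R'
    'minigenome.R'
    'pipeline.R'
    'replicon.R'
    'rnaseq.R'
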
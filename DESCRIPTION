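Package: sixpep
Title: Peptidogenomics with Coordinate-Tracked Six-Frame Translation
    Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds coordinate-tracked six-frame translation databases
    from genomic sequence, assigns mass-spectrometry-identified
    endogenous peptides to unique genomic loci, and classifies them as
    conventional peptides (in-frame CDS) or non-conventional peptides
    (intergenic, intronic, UTR, or out-of-frame exonic) against gene
    models. Includes chromosome-scale density and hotspot statistics,
    physicochemical characterization (molecular weight, isoelectric
    point, hydropathy composition, genomic start codons),
    tissue-expression pattern classification, non-coding RNA and
    ribosome-profiling support assessment, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
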
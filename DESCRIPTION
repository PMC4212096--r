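Package: rrhp
Title: Reduced Representation 5-Hydroxymethylcytosine Profiling Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for reduced representation
    5-hydroxymethylcytosine profiling (RRHP), a positive-display assay in
    which genomic DNA is digested with MspI, adapter-ligated so the CCGG
    site is reconstituted at the P5 junction, glucosylated with
    beta-glucosyltransferase, and re-digested so that only fragments
    carrying glucosyl-5hmC at the junction are amplified and sequenced.
    Provides in silico MspI digestion with fragment size selection and a
    catalog of detectable CCGG junction sites; a molecule-level simulator
    of the library chemistry (glucosylation on/off, MspI or HpaII second
    digestion, incomplete digestion, PCR duplication, sequencing error)
    emitting FASTQ reads with a ground-truth table; a CCGG-tag junction
    profiler producing strand-specific per-site read counts from SAM/BAM
    alignments or via a built-in exact junction matcher; replicate QC
    statistics (coverage distributions, Pearson correlation, site overlap,
    strand asymmetry, paired differential ranking); RRBS-anchored
    false-call calibration with minimal read-cutoff selection; and
    glucMS-qPCR 5hmC quantitation from Ct values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
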
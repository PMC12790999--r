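Package: cfphase
Title: Cell-Free DNA Fragmentomics, Nucleosome Footprinting and Composition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical toolkit for the circulating cell-free DNA (cfDNA)
    "circulome": fragment-length distributions, size-class proportions and
    fragmentation indices; 5'-oriented 4-bp fragment end-motif frequencies with
    genome-expected baselines and differential-usage testing; windowed
    protection score (WPS) nucleosome footprinting around transcription start
    sites; a two-stage damped-harmonic-oscillator model quantifying nucleosome
    phasing; genome-equivalent and cellular-turnover estimation; hierarchical
    reference-based methylome deconvolution; and microbial read-count outlier
    detection. Includes a synthetic-data generator that emulates phased
    nucleosome arrays, cleavage end-motif biases, cell-type methylation
    mixtures and contaminated genus count tables, so every analysis can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
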
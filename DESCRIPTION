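Package: recfst
Title: Allele-Frequency Differentiation and Local Recombination Rate
Version: 1.0.0
Authors@R:
    person("recfst", "developers", email = "recfst@example.org",
           role = c("aut", "cre"))
Description: Tools for relating SNP allele-frequency differentiation (FST)
    between populations to the local recombination rate. Provides
    recombination-rate annotation of SNPs from a genetic map (windowed
    cM/Mb with centromere/telomere validity filters), variance-corrected
    ratio-of-sums FST estimation (pairwise and global, with a
    Weir-Cockerham cross-check), equal-occupancy binning by recombination
    rate with linear and quadratic regression of FST on rate, and a
    moving-block-bootstrap inference framework with z-tests and
    between-analysis comparisons that accounts for linkage disequilibrium
    between neighbouring SNPs. Includes a synthetic-data generator that
    plants a Balding-Nichols FST-recombination relationship with
    block-structured LD for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    data.table,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
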
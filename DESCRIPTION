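Package: bulkscan
Title: Bulked-Segregant QTL Mapping for Recombinant Inbred Line Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps quantitative trait loci from pooled whole-genome sequencing
    of the phenotypic extremes of a recombinant inbred line (RIL) panel
    (bulked segregant analysis). Implements allele-frequency extraction from
    two-bulk VCFs, genotype-quality and depth filters, a bulk-size-scaled
    log10 odds statistic over non-overlapping 300-kb windows, genome-wide
    significance thresholds from a simulated (or exactly enumerated)
    Bernoulli null, QTL interval calling, and LOESS frequency smoothing.
    Includes a forward simulator of the underlying two-parent cross
    (meiosis, selfing, bulk selection, pooled read counts) so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
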
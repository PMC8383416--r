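Package: circaccess
Title: Chromatin Accessibility of Circular Extrachromosomal DNA from
    Long-Read m6A Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects circular extrachromosomal DNA (ecDNA) from split
    long-read alignments via head-to-tail junction geometry, builds rotated
    and N-padded circular reference sequences with exact coordinate liftover,
    derives a true-m6A probability cutoff from a two-component Gaussian
    mixture fitted to per-read modified-base probabilities, computes bulk and
    single-molecule chromatin accessibility profiles on circular and linear
    DNA, and quantifies single-molecule co-accessibility between genomic
    windows. A fully synthetic data generator with known ground truth
    (nucleosome landscapes, circle junctions, per-base methylation
    probabilities) supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
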
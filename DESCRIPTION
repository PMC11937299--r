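Package: lignims
Title: Arrayed Mass Spectrometry Imaging Analysis of Lignin Model-Dimer
    Enzyme Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput enzyme screens read out by
    mass spectrometry imaging (MSI) of dried-droplet arrays of NIMS-tagged
    lignin model dimers. Detects per-pixel peaks with the alternating-extrema
    (peakdet) algorithm, locates the arrayed sample spots on the raster,
    consolidates peaks into +/-0.1 m/z bins, classifies ions by mass offset
    from the substrate into unreacted, modified, cleaved and polymerized
    categories, and computes per-spot relative proportions. Downstream
    statistics include one-sided Dunnett many-to-one comparisons against
    no-enzyme controls, pH activity-range calling, pH-product correlations and
    time-course ion tracking. A synthetic-raster generator with known ground
    truth supports end-to-end validation, and imzML plus a documented internal
    container are supported for raster I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mvtnorm,
    pracma,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
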
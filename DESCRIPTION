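Package: pollenkin
Title: Parentage, Pollen Dispersal and Mating-System Analysis for Spaced-Plant Nurseries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based paternity assignment with simulation-calibrated
    confidence thresholds, mixed-mating outcrossing-rate estimation, pollen
    dispersal kernels and axial variance, correlated paternity, distance-binned
    genetic diversity, and single-environment GBLUP genomic prediction for
    wind-pollinated spaced-plant breeding nurseries genotyped with biallelic
    SNPs. Includes a forward simulator of such a nursery that records ground
    truth (true fathers, selfing events, kernel parameters) so every stage of
    the analysis is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
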
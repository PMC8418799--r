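Package: msatIBD
Title: Microsatellite Locus Quality Screening and Isolation-by-Distance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing and improving the signal-to-noise ratio of
    diploid microsatellite (SSR) datasets before spatial-genetic-structure
    analysis. Implements per-locus noise metrics (homozygote-excess null-allele
    detection with Brookfield frequency estimation, a repeat-count homoplasy
    proxy rescaled to the median-sized allele), inbred-population screening via
    U-tests of heterozygote deficiency, rank-based iterative locus omission
    with a one-tailed Welch t-test stopping rule, and per-locus Weir-Cockerham
    F_ST ranking for high-signal locus retention. Population-based (chord,
    Nei standard, linearized F_ST) and individual-based (kinship, shared
    alleles, Lynch-Ritland relatedness) genetic distances feed one-tailed
    Mantel tests of isolation by distance against Haversine geographic
    distances. A forward-time stepping-stone simulator with stepwise mutation,
    sex-biased dispersal and null alleles generates datasets with the
    statistical structure the analysis assumes. GenePop-format input and
    output are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
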
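Package: ovotransfer
Title: Harmonized Databases of Maternal Transfer of Organic Pollutants in Oviparous Reptiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyzes harmonized databases of organic-pollutant
    concentrations measured in paired reptile mothers and their offspring.
    Ingests per-study tabular records with heterogeneous units, measurement
    bases and censoring conventions; converts all concentrations (and their
    detection limits) to ng/g on wet-weight and lipid-normalized bases using
    reported lipid contents with a literature fallback chain and a dry-to-wet
    water-content conversion; annotates compounds with molecular descriptors
    (log Kow, molecular weight, topological polar surface area and others)
    under an explicit provenance policy covering coelutions and sums of
    compounds; audits three-state censoring (uncensored, quantitatively and
    qualitatively censored); and computes mother-to-offspring partition
    ratios, ten-fold equilibrium banding, tissue-tissue correlations, and
    partition-ratio trends against log Kow. Includes a seeded generator of
    synthetic multi-study mother-offspring datasets with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
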
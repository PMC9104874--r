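Package: carrierscan
Title: Carrier Enrichment and Variant Prioritization for Founder-Population
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing rare germline variants in founder-population
    case-control studies of hereditary cancer: quality and frequency filtering
    of annotated variant calls, in-silico predictor based prioritization of
    candidate variants, carrier-frequency tabulation with two-sided Fisher's
    exact tests, a permutation study of carrier re-allocation across study
    groups with family-wise error rate estimation, loss-of-heterozygosity
    classification from tumour/normal allele fractions, clinico-pathological
    summaries, and a synthetic-data generator that emulates the study design
    so every stage can be exercised without access to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
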
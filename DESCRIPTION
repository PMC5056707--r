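Package: gsikit
Title: Genetic Stock Identification with SNP Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SNP-based genetic stock identification (GSI) of
    salmonids sampled in hierarchical baselines (sites within rivers within
    regions). Implements locus quality control with exact Hardy-Weinberg
    tests, Weir-Cockerham F_ST locus ranking and nested panel selection,
    Rannala-Mountain Bayesian individual assignment with score cut-offs,
    iterative definition of assignment units meeting an accuracy threshold,
    and EM-based mixed-stock analysis with parametric resampling of baseline
    allele frequencies. Includes a Balding-Nichols simulator of hierarchical
    baselines and fishery mixtures with known composition, so the whole
    workflow can be exercised end-to-end on data with known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
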
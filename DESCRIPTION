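Package: triadr
Title: Construction and Statistical Assessment of RNA-Protein-DNA Interaction Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters noisy RNA-chromatin contact data through protein-DNA
    (ChIP-seq) and protein-RNA (RIP/fRIP/eCLIP) interval evidence to build
    RNA-protein-DNA interaction triads, assesses their significance against
    structure-preserving permutation null models (compartment-aware ChIP peak
    shifts and relatedness-constrained protein-RNA peak resampling), and scores
    and annotates the resulting triads: harmonic-mean q-value aggregation,
    distance-scaling contact weights, cis/trans shift tests, chromatin-state
    enrichment, A/B-compartment densities, and cross-protocol consistency.
    Includes a synthetic-data generator emulating the statistical structure of
    RNA-chromatin interactome data with planted triads and a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
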
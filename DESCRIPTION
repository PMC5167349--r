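Package: covbias
Title: Enzyme-Processivity Models of RNA-Seq Coverage Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic models of RNA-seq library preparation in which
    first- and second-strand cDNA synthesis lengths are exponentially
    distributed with rates given by the inverse enzyme processivities.
    Provides closed-form read-start coverage densities and their areas
    (length-dependent correction factors) for five library-preparation
    scenarios and a two-component mixture, a stochastic simulator of the
    same generative process, adaptive-Metropolis MCMC inference of
    processivity and fragmentation parameters from per-transcript read
    start positions, likelihood-ratio model comparison, and coverage
    diagnostics (binned coverage matrices, entropy-based uniformity
    metrics, and area-corrected transcript abundances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
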
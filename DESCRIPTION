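Package: diauxnet
Title: Inference of Substrate Inhibition Networks from Batch-Culture Growth Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to infer pairwise substrate-inhibition networks from
    single-species batch-culture growth data. Implements a dynamic energy
    budget (DEB) growth model with Monod-type inhibited uptake kinetics,
    a scale-invariant depletion-curve dissimilarity with hierarchical
    clustering of substrates into identifiability classes, decoupled
    per-substrate uptake fitting against interpolated observations, an
    incremental interaction scan ranked by R-squared improvement,
    replicate-subset resampling of interaction estimates, a joint fit of
    the full growth model, and a synthetic-experiment generator with
    planted interaction networks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
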
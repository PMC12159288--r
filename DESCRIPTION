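Package: anibench
Title: Benchmarking Average Nucleotide Identity Estimators Against Tree Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for benchmarking estimators of average
    nucleotide identity (ANI) and related genome distances against a known
    phylogeny. Implements k-mer set Jaccard, bottom-s MinHash sketching and the
    Mash distance; alignment-based estimators (fragment ANIb, reciprocal-best-hit
    OrthoANI, a NUCmer-like maximal-exact-match anchor/chain/extend pipeline with
    MUM and MEM modes and 1-to-1 filtering, alignment-fraction weighting, and the
    digital-DDH distance formulas); a birth-death genome-evolution simulator with
    indels, gene duplication and lateral gene transfer that emits genomes with a
    known true tree and event log; and a rank-correlation evaluation engine that
    scores how well each estimator recovers patristic or topological tree
    distance, with Spearman p-values computed in log space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
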
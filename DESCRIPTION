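Package: boolcarve
Title: Attractor-Landscape Decomposition of Boolean Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing Boolean models of signaling networks into
    an evolvable core and a robust neighbor based on their attractor
    landscape. Provides synchronous and asynchronous Boolean dynamics,
    sampled and exact attractor-landscape estimation with basin-of-attraction
    sizes, an edge-knockout decomposition algorithm driven by preservation of
    the primary attractor, topological null-model statistics (feedback-loop
    census, degree heterogeneity, characteristic path length), canalizing
    function and redundant-link analysis via exact two-level logic
    minimization, gene-level score enrichment with permutation tests, and a
    seeded random Boolean network generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
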
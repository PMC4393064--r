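Package: nucvote
Title: Consensus Voting over Nucleosome Position Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Combines nucleosome position calls from multiple prediction
    methods ("voters") into consensus nucleosome maps. Calls from different
    voters whose centers lie within half a nucleosome of each other are
    grouped into consensus areas; each voter is ranked by how strongly its
    call occupancies anti-correlate with the center spread of those areas,
    and the call of the best-ranked voter is emitted per area. Includes a
    synthetic nucleosome-map simulator (stable lattice plus fuzzy
    nucleosomes with strand-specific tag sampling), three simplified
    reference callers (Gaussian-smoothed peak calling, triangular
    center-density calling, template boundary matching), per-base-pair and
    center-distance evaluation metrics, and transcription start site
    profiling with nucleosome-free region detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
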
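Package: pathspread
Title: Directionality-Biased Network Diffusion Models of Pathology Spread
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spread of pathological proteins (such as misfolded
    alpha-synuclein) over a directed, weighted mesoscale brain connectome as
    graph-Laplacian diffusion with a continuous anterograde/retrograde
    directionality parameter, global amplification/clearance, seed scaling,
    and optional gene-expression modulation of outgoing and/or incoming
    connections. Provides Lin's concordance correlation coefficient as the
    fitting objective on log10-transformed regional burdens, bounded
    multi-start parameter estimation, connectome robustness analyses (null
    connectomes, random and strength-ordered edge removal, key-connectome
    extraction), genome-wide per-gene screening with permutation bootstraps,
    over-representation and key-driver statistics for candidate gene sets,
    and synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    lhs,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
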
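Package: spreadrank
Title: Identifying Influential Spreaders in Networks with a Degree/K-Shell Gravity Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks nodes of undirected contact networks by spreading influence.
    Implements a k-shell decomposition that records the removal stage of every
    node, the resulting high-resolution improved k-shell index and combined
    degree/k-shell (DK) index, and a truncated gravity-law centrality family
    (DKGM, gravity centrality, local gravity model). Ships the classic
    benchmark centralities (degree, k-shell, H-index, betweenness, closeness),
    a discrete-time SIR epidemic simulator that produces the standard influence
    ranking, and the evaluation metrics (Kendall's tau with tie exclusion,
    ranking monotonicity) used to compare methods, together with edge-list
    input/output, synthetic graph generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
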
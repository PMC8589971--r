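#' The 9-node illustration network
#'
#' A small fixed network whose k-shell peeling needs two stages inside the
#' 2-shell, so that nodes tied under both degree and plain k-shell value
#' become distinguishable under the improved index. Nodes are labelled
#' "1".."9"; degree sequence (1, 3, 3, 4, 4, 4, 5, 1, 1).
#'
#' @return a `spread_network` with N = 9, M = 13
#' @examples
#' degrees(toy_network())
#' @export
toy_network <- function() {
  e <- rbind(c(1, 2), c(2, 3), c(2, 7), c(3, 4), c(3, 7),
             c(4, 5), c(4, 6), c(4, 7), c(5, 6), c(5, 7),
             c(6, 7), c(5, 8), c(6, 9))
  new_network(e, as.character(1:9))
}

#' Seeded random graph generators
#'
#' Thin wrappers over the standard igraph generators, returning a
#' `spread_network` with labels "1".."n". Kinds:
#' \describe{
#'   \item{er}{Erdos-Renyi G(n, p); parameter `p`}
#'   \item{ba}{Barabasi-Albert preferential attachment; parameter `m`
#'     edges per new node (so M = m(n - m) + choose(m, 2))}
#'   \item{ws}{Watts-Strogatz ring rewiring; parameters `nei` (lattice
#'     half-width) and `p` (rewiring probability)}
#'   \item{tree}{uniform random labelled tree (M = n - 1), the sparse
#'     tree-like regime where few alternative paths exist}
#' }
#'
#' @param kind one of `"er"`, `"ba"`, `"ws"`, `"tree"`
#' @param n number of nodes (>= 2)
#' @param p edge probability (er) or rewiring probability (ws)
#' @param m edges added per node (ba)
#' @param nei lattice neighbourhood half-width (ws)
#' @param rng_seed optional integer seed; same seed, same edge set
#' @return a `spread_network`
#' @examples
#' g <- random_graph("ba", n = 50, m = 3, rng_seed = 7)
#' g$m  # 3 * 47 + 3
#' @export
random_graph <- function(kind = c("er", "ba", "ws", "tree"), n,
                         p = NULL, m = NULL, nei = NULL, rng_seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be at least 2")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  g <- switch(kind,
    er = {
      if (is.null(p) || p < 0 || p > 1) stop("er requires p in [0, 1]")
      igraph::sample_gnp(n, p)
    },
    ba = {
      if (is.null(m) || m < 1L || m >= n) stop("ba requires 1 <= m < n")
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    ws = {
      if (is.null(nei) || nei < 1L) stop("ws requires nei >= 1")
      if (is.null(p) || p < 0 || p > 1) stop("ws requires p in [0, 1]")
      igraph::sample_smallworld(1, n, nei, p)
    },
    tree = igraph::sample_tree(n, method = "prufer")
  )
  g <- igraph::simplify(g)
  net <- from_igraph(g)
  net$labels <- as.character(seq_len(net$n))
  names(net$adj) <- NULL
  net
}
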
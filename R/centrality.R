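#' Degree centrality
#'
#' DC(i) = k(i), the number of neighbours of node i.
#'
#' @param net a `spread_network`
#' @return named numeric vector of degrees
#' @export
degree_centrality <- function(net) {
  d <- degrees(net)
  stats::setNames(as.numeric(d), names(d))
}

#' k-shell centrality
#'
#' The plain shell value k_s(i) from the k-shell decomposition, as a score
#' vector (the classic KS benchmark).
#'
#' @param net a `spread_network`
#' @return named numeric vector of shell values
#' @export
kshell_centrality <- function(net) {
  s <- kshell_decompose(net)$shell
  stats::setNames(as.numeric(s), names(s))
}

#' H-index centrality
#'
#' H(i) is the largest integer h such that node i has at least h neighbours
#' whose degree is at least h. Degree-0 nodes score 0.
#'
#' @param net a `spread_network`
#' @return named numeric vector
#' @export
h_index <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  k <- lengths(net$adj)
  h <- vapply(net$adj, function(nb) {
    if (length(nb) == 0L) return(0)
    nd <- sort(k[nb], decreasing = TRUE)
    sum(nd >= seq_along(nd))
  }, numeric(1))
  stats::setNames(h, net$labels)
}

#' Shortest-path betweenness centrality
#'
#' Unnormalised betweenness over unordered node pairs \{s, t\} with
#' s != i != t: the sum of the fractions of shortest s-t paths passing
#' through i. Pairs in different components contribute 0.
#'
#' @param net a `spread_network`
#' @return named numeric vector
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  b <- igraph::betweenness(as_igraph(net), directed = FALSE, weights = NULL)
  stats::setNames(as.numeric(b), net$labels)
}

#' Closeness centrality (component-scaled)
#'
#' On a connected graph this is (N - 1) / sum_j d(i, j). On a disconnected
#' graph the sum runs over the n_i nodes reachable from i and the result is
#' scaled by n_i / (N - 1), i.e. CC(i) = (n_i / sum d) * (n_i / (N - 1)),
#' which penalises nodes in small components. Degree-0 nodes score 0.
#'
#' @param net a `spread_network` with at least 2 nodes
#' @return named numeric vector
#' @export
closeness_centrality <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  if (net$n < 2L) stop("closeness needs at least 2 nodes")
  dmat <- igraph::distances(as_igraph(net))
  cc <- vapply(seq_len(net$n), function(i) {
    d <- dmat[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0L) return(0)
    (length(d) / sum(d)) * (length(d) / (net$n - 1))
  }, numeric(1))
  stats::setNames(cc, net$labels)
}

#' Compute a named ranking method's scores
#'
#' Dispatcher used by the evaluation harness and the command-line
#' interface. Method names: `dc`, `ks`, `ksstar`, `dk`, `hindex`, `bc`,
#' `cc`, `gc`, `lgm`, `dkgm`.
#'
#' @param net a `spread_network`
#' @param method method name (see above)
#' @param radius truncation radius for the gravity methods; `NULL` means
#'   the [optimal_radius()] heuristic for `dkgm`/`lgm` and 3 for `gc`
#' @return named numeric vector of scores
#' @export
score_method <- function(net, method, radius = NULL) {
  switch(method,
    dc     = degree_centrality(net),
    ks     = kshell_centrality(net),
    ksstar = improved_kshell(net),
    dk     = dk_index(net),
    hindex = h_index(net),
    bc     = betweenness_centrality(net),
    cc     = closeness_centrality(net),
    gc     = gravity_centrality(net, radius = if (is.null(radius)) 3 else radius),
    lgm    = local_gravity(net, radius = radius),
    dkgm   = dkgm(net, radius = radius),
    stop("unknown method: ", method)
  )
}
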
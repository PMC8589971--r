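#' @useDynLib spreadrank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a spread_network from an edge matrix
#'
#' Internal constructor. Edges are given as a two-column matrix of 1-based
#' node indices; self-loops are dropped and duplicate edges collapsed so the
#' result is always a simple undirected graph.
#'
#' @param edges two-column integer matrix of node indices (may have 0 rows)
#' @param labels character vector of node labels, one per node
#' @return an object of class `spread_network` with fields `labels`,
#'   `adj` (per-node integer vector of neighbour indices), `n`, `m` and
#'   `edges` (canonical two-column matrix with `edges[,1] < edges[,2]`)
#' @keywords internal
new_network <- function(edges, labels) {
  n <- length(labels)
  stopifnot(is.character(labels), !anyDuplicated(labels))
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) stop("edge index out of range")
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]   # self-loops
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[!duplicated(edges), , drop = FALSE]           # multi-edges
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  adj <- rep(list(integer(0)), n)
  if (nrow(edges) > 0L) {
    half <- split(c(edges[, 2L], edges[, 1L]),
                  factor(c(edges[, 1L], edges[, 2L]), levels = seq_len(n)))
    adj <- lapply(half, function(v) sort(as.integer(v)))
  }
  structure(list(labels = labels, adj = adj, n = n,
                 m = nrow(edges), edges = edges),
            class = "spread_network")
}

#' Build a network from a two-column label matrix
#'
#' Labels are mapped to indices in order of first appearance (row-major
#' across the two columns), the convention used when reading edge lists.
#'
#' @param pairs two-column character matrix of endpoint labels
#' @return a [spread_network][new_network]
#' @keywords internal
network_from_pairs <- function(pairs) {
  pairs <- matrix(as.character(pairs), ncol = 2L)
  labels <- unique(as.vector(t(pairs)))
  idx <- matrix(match(pairs, labels), ncol = 2L)
  new_network(idx, labels)
}

#' Read an undirected network from a plain-text edge list
#'
#' One edge per line as two whitespace-separated node labels; extra tokens
#' on a line are ignored, blank lines and lines starting with `#` are
#' skipped. Labels are opaque strings kept in first-appearance order.
#' Self-loops are dropped and duplicate edges collapsed.
#'
#' @param path path to the edge-list file
#' @return a `spread_network` object
#' @examples
#' f <- tempfile()
#' writeLines(c("# comment", "a b", "b c", "b a"), f)
#' net <- load_edge_list(f)
#' net$n  # 3 nodes
#' net$m  # 2 edges: the duplicate "b a" collapses onto "a b"
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nums <- which(keep)
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L)
    stop("line ", nums[bad[1L]], ": expected two node labels, got one")
  pairs <- t(vapply(toks, function(x) x[1:2], character(2)))
  if (nrow(pairs) == 0L) return(new_network(matrix(integer(0), ncol = 2), character(0)))
  network_from_pairs(pairs)
}

#' Write a network as a plain-text edge list
#'
#' Inverse of [load_edge_list()]: reloading the written file recovers the
#' same labelled graph. Isolated nodes cannot be represented in an edge
#' list and trigger a warning.
#'
#' @param net a `spread_network`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "spread_network"))
  if (any(lengths(net$adj) == 0L))
    warning("isolated nodes are not representable in an edge list and will be lost")
  lines <- paste(net$labels[net$edges[, 1L]], net$labels[net$edges[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Convert a spread_network to an igraph graph
#'
#' @param net a `spread_network`
#' @return an undirected simple `igraph` graph with vertex names = labels
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  g <- igraph::make_empty_graph(n = net$n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$labels)
  if (net$m > 0L) g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Convert an igraph graph to a spread_network
#'
#' @param g an undirected igraph graph; multi-edges and loops are simplified
#' @return a `spread_network`; vertex names are used as labels when present,
#'   otherwise vertices are labelled "1".."n"
#' @export
from_igraph <- function(g) {
  labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)))
  new_network(igraph::as_edgelist(g, names = FALSE), as.character(labels))
}

#' Node degrees
#' @param net a `spread_network`
#' @return named integer vector of degrees (names = labels)
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  stats::setNames(lengths(net$adj), net$labels)
}

#' @export
print.spread_network <- function(x, ...) {
  cat("spread_network:", x$n, "nodes,", x$m, "edges\n")
  invisible(x)
}

# Radius-limited breadth-first search over the adjacency list.
# Returns integer distances indexed by node (NA = unreachable or beyond
# `radius`); dist[source] = 0.
bfs_idx <- function(net, source, radius = Inf) {
  dist <- rep(NA_integer_, net$n)
  dist[source] <- 0L
  frontier <- source
  d <- 0L
  while (length(frontier) > 0L && d < radius) {
    d <- d + 1L
    nxt <- unique(unlist(net$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Hop distances from a source node
#'
#' Exact unweighted shortest-path distances by breadth-first search,
#' optionally truncated at a radius. Unreachable (or beyond-radius) nodes
#' are absent from the result.
#'
#' @param net a `spread_network`
#' @param source node label (string) or 1-based index
#' @param radius maximum distance to explore (default unbounded)
#' @return named integer vector of distances, including `source` at 0
#' @export
bfs_distances <- function(net, source, radius = Inf) {
  stopifnot(inherits(net, "spread_network"))
  src <- node_index(net, source)
  d <- bfs_idx(net, src, radius)
  keep <- !is.na(d)
  stats::setNames(d[keep], net$labels[keep])
}

# Resolve a node given as label or index; errors on anything invalid.
node_index <- function(net, node) {
  if (is.character(node)) {
    i <- match(node, net$labels)
    if (is.na(i)) stop("unknown node label: ", node)
    return(i)
  }
  i <- as.integer(node)
  if (is.na(i) || i < 1L || i > net$n) stop("node index out of range: ", node)
  i
}

#' Descriptive network statistics
#'
#' The standard summary row for a contact network: size, mean degree
#' \eqn{\langle k\rangle}, mean shortest-path distance \eqn{\langle d\rangle}
#' (averaged over reachable pairs only), mean local clustering coefficient
#' \eqn{C} (nodes of degree < 2 contribute 0), degree assortativity \eqn{r},
#' degree heterogeneity \eqn{H = \langle k^2\rangle/\langle k\rangle^2}, and
#' the heterogeneous mean-field epidemic threshold
#' \eqn{\beta_c = \langle k\rangle/(\langle k^2\rangle - \langle k\rangle)}.
#'
#' @param net a `spread_network` with at least 2 nodes
#' @return an object of class `network_stats`: a list with elements `n`, `m`,
#'   `mean_degree`, `mean_distance`, `clustering`, `assortativity`,
#'   `heterogeneity`, `second_moment`, `epidemic_threshold`
#' @examples
#' network_stats(toy_network())
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  if (net$n < 2L) stop("network_stats needs at least 2 nodes")
  g <- as_igraph(net)
  k <- lengths(net$adj)
  k2 <- mean(k^2)
  kbar <- mean(k)
  if (net$m == 0L) {
    warning("network has no edges: assortativity and epidemic threshold undefined")
    r <- NaN
    bc <- NaN
    dbar <- NaN
  } else {
    r <- igraph::assortativity_degree(g, directed = FALSE)
    bc <- if (k2 > kbar) kbar / (k2 - kbar) else {
      warning("second degree moment <= mean degree: epidemic threshold undefined")
      NaN
    }
    dbar <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  }
  cloc <- igraph::transitivity(g, type = "local", isolates = "zero")
  structure(list(
    n = net$n, m = net$m,
    mean_degree = kbar,
    mean_distance = dbar,
    clustering = if (net$n > 0L) mean(cloc) else NaN,
    assortativity = r,
    heterogeneity = k2 / kbar^2,
    second_moment = k2,
    epidemic_threshold = bc
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, digits = 4, ...) {
  v <- c(N = x$n, M = x$m, `<k>` = x$mean_degree, `<d>` = x$mean_distance,
         C = x$clustering, r = x$assortativity, H = x$heterogeneity,
         beta_c = x$epidemic_threshold)
  print(round(v, digits))
  invisible(x)
}
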
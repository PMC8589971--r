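#' Truncated gravity-law node score
#'
#' Generic engine for the gravity centrality family: each node i scores
#' \deqn{\sum_{j \ne i,\; 1 \le d(i,j) \le R} \frac{m(i)\, m(j)}{d(i,j)^2}}
#' where m is a per-node mass and d the hop distance. Neighbourhoods are
#' found by radius-limited breadth-first search from each node; pairs in
#' different components never contribute. Instantiations: mass = DK index
#' gives [dkgm()], mass = k-shell value with R = 3 gives
#' [gravity_centrality()], mass = degree gives [local_gravity()].
#'
#' @param net a `spread_network`
#' @param mass named non-negative numeric vector covering all nodes
#' @param radius truncation radius R, a positive integer (hops)
#' @return named numeric vector of gravity scores; isolated nodes score 0
#' @export
gravity_score <- function(net, mass, radius) {
  stopifnot(inherits(net, "spread_network"))
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("radius must be a positive integer")
  if (!all(net$labels %in% names(mass)))
    stop("mass must cover every node of the network")
  if (any(mass < 0)) stop("mass must be non-negative")
  m <- as.numeric(mass[net$labels])
  out <- numeric(net$n)
  for (i in seq_len(net$n)) {
    d <- bfs_idx(net, i, radius)
    j <- which(!is.na(d) & d > 0L)
    if (length(j) > 0L) out[i] <- sum(m[i] * m[j] / d[j]^2)
  }
  stats::setNames(out, net$labels)
}

#' DK-based gravity model (DKGM)
#'
#' The full pipeline: staged k-shell decomposition, improved k-shell index,
#' DK index, then the truncated gravity score with the DK values as masses.
#'
#' @param net a `spread_network`
#' @param radius truncation radius R; `NULL` (default) picks
#'   [optimal_radius()] of the network's mean distance
#' @return named numeric vector of DKGM scores
#' @examples
#' round(dkgm(toy_network(), radius = 2), 2)  # node 7 -> 289.58
#' @export
dkgm <- function(net, radius = NULL) {
  if (is.null(radius)) radius <- auto_radius(net)
  gravity_score(net, dk_index(net), radius)
}

#' Gravity centrality (k-shell mass)
#'
#' Gravity score with plain k-shell values as masses and a fixed truncation
#' radius of 3 hops.
#'
#' @param net a `spread_network`
#' @param radius truncation radius, conventionally 3
#' @return named numeric vector
#' @export
gravity_centrality <- function(net, radius = 3) {
  gravity_score(net, as.numeric(kshell_decompose(net)$shell) |>
                  stats::setNames(net$labels), radius)
}

#' Local gravity model (degree mass)
#'
#' Gravity score with node degrees as masses.
#'
#' @inheritParams dkgm
#' @return named numeric vector
#' @export
local_gravity <- function(net, radius = NULL) {
  if (is.null(radius)) radius <- auto_radius(net)
  gravity_score(net, as.numeric(degrees(net)) |> stats::setNames(net$labels),
                radius)
}

#' Heuristic optimal truncation radius
#'
#' R* is approximately half the network's mean shortest-path distance.
#' The real value is rounded half-up and clamped below at 1 so the result
#' is a usable integer radius.
#'
#' @param mean_distance positive mean distance \eqn{\langle d\rangle}
#' @return positive integer radius
#' @examples
#' optimal_radius(18.9892)  # 9
#' @export
optimal_radius <- function(mean_distance) {
  if (!is.finite(mean_distance) || mean_distance <= 0)
    stop("mean_distance must be positive")
  max(1L, as.integer(floor(mean_distance / 2 + 0.5)))
}

# Resolve the default radius for a network from its mean distance.
auto_radius <- function(net) {
  g <- as_igraph(net)
  if (net$m == 0L) return(1L)
  optimal_radius(igraph::mean_distance(g, directed = FALSE, unconnected = TRUE))
}
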
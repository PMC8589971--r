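# CSR adjacency (0-based) for the compiled SIR core.
csr_adjacency <- function(net) {
  list(adj = as.integer(unlist(net$adj, use.names = FALSE) - 1L),
       ptr = as.integer(c(0L, cumsum(lengths(net$adj)))))
}

#' Simulate one SIR outbreak
#'
#' Discrete-time synchronous susceptible-infected-recovered dynamics:
#' the process starts with `seed_node` infected and all other nodes
#' susceptible; each step, every infected node independently infects each
#' susceptible neighbour with probability `beta`, then recovers (with
#' probability `lambda`, default 1, so a node is infectious for exactly one
#' step). The process stops when no infected nodes remain.
#'
#' Randomness comes from R's global RNG: call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param net a `spread_network`
#' @param seed_node seed node label or index
#' @param beta infection probability per infected-susceptible contact per
#'   step, in \[0, 1\]
#' @param lambda recovery probability per step (default 1)
#' @return integer: the final number of recovered nodes (at least 1)
#' @export
simulate_outbreak <- function(net, seed_node, beta, lambda = 1) {
  stopifnot(inherits(net, "spread_network"), beta >= 0, beta <= 1,
            lambda > 0, lambda <= 1)
  src <- node_index(net, seed_node)
  csr <- csr_adjacency(net)
  sir_outbreak_cpp(csr$adj, csr$ptr, src - 1L, beta, lambda)
}

#' SIR spreading influence of every node
#'
#' The standard ranking against which centrality methods are judged:
#' F(i) is the mean final recovered fraction N_r / N over `realizations`
#' independent outbreaks seeded at node i alone. Each realization runs one
#' outbreak from every node.
#'
#' @param net a `spread_network`
#' @param beta infection probability; `"auto"` uses [epidemic_threshold()]
#' @param realizations number of independent realizations (default 1000)
#' @param rng_seed optional integer seed; identical seed and configuration
#'   give bit-identical results
#' @param lambda recovery probability (default 1)
#' @return an object of class `sir_influence`: a list with `influence`
#'   (named numeric vector of F(i), each in \[1/N, 1\]), `beta`, `lambda`,
#'   and `realizations`
#' @examples
#' net <- toy_network()
#' inf <- sir_influence(net, beta = 0.3, realizations = 50, rng_seed = 1)
#' round(inf$influence, 3)
#' @export
sir_influence <- function(net, beta, realizations = 1000, rng_seed = NULL,
                          lambda = 1) {
  stopifnot(inherits(net, "spread_network"))
  if (identical(beta, "auto")) beta <- epidemic_threshold(net)
  stopifnot(beta >= 0, beta <= 1, realizations >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  csr <- csr_adjacency(net)
  mean_nr <- sir_influence_cpp(csr$adj, csr$ptr, beta, lambda,
                               as.integer(realizations))
  structure(list(
    influence = stats::setNames(mean_nr / net$n, net$labels),
    beta = beta, lambda = lambda,
    realizations = as.integer(realizations)
  ), class = "sir_influence")
}

#' @export
print.sir_influence <- function(x, ...) {
  cat("sir_influence: beta =", signif(x$beta, 4), "lambda =", x$lambda,
      "realizations =", x$realizations, "\n")
  print(round(x$influence, 4))
  invisible(x)
}

#' Heterogeneous mean-field epidemic threshold
#'
#' \eqn{\beta_c \approx \langle k\rangle / (\langle k^2\rangle -
#' \langle k\rangle)}, the critical infection probability of the SIR model
#' with one-step recovery. Undefined when the second degree moment does not
#' exceed the mean degree (e.g. an empty graph or a perfect matching).
#'
#' @param net a `spread_network`
#' @return the threshold, a positive real
#' @examples
#' epidemic_threshold(toy_network())  # 26/68
#' @export
epidemic_threshold <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  k <- lengths(net$adj)
  kbar <- mean(k)
  k2 <- mean(k^2)
  if (k2 <= kbar)
    stop("epidemic threshold undefined: <k^2> <= <k>")
  kbar / (k2 - kbar)
}
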
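#' k-shell decomposition with removal-stage tracking
#'
#' Iteratively peels the network by shell value k = 0, 1, 2, ... For shell k,
#' all remaining nodes of current degree <= k are removed *simultaneously*;
#' each such simultaneous sweep is one stage, numbered from 1, and sweeps
#' repeat until no remaining node qualifies. The stage records how late a
#' node falls within its shell, which is what lets the improved k-shell
#' index break ties that plain k-shell values cannot. Isolated nodes form a
#' 0-shell removed at stage 1.
#'
#' @param net a `spread_network`
#' @return an object of class `shell_decomposition`: a list with
#'   \describe{
#'     \item{shell}{named integer vector, k-shell value of each node}
#'     \item{stage}{named integer vector, removal sweep (within its shell)}
#'     \item{stage_counts}{named integer vector q(k), number of sweeps per
#'       occurring shell value k}
#'     \item{max_stage_count}{max over k of q(k)}
#'   }
#' @examples
#' dec <- kshell_decompose(toy_network())
#' dec$shell          # 1 2 2 3 3 3 3 1 1
#' dec$stage_counts   # q(1)=1, q(2)=2, q(3)=1
#' @export
kshell_decompose <- function(net) {
  stopifnot(inherits(net, "spread_network"))
  n <- net$n
  shell <- integer(n)
  stage <- integer(n)
  deg <- lengths(net$adj)
  alive <- rep(TRUE, n)
  qk <- integer(0)
  k <- 0L
  while (any(alive)) {
    if (any(deg[alive] <= k)) {
      s <- 0L
      repeat {
        sweep <- which(alive & deg <= k)
        if (length(sweep) == 0L) break
        s <- s + 1L
        shell[sweep] <- k
        stage[sweep] <- s
        alive[sweep] <- FALSE
        touched <- unlist(net$adj[sweep], use.names = FALSE)
        touched <- touched[alive[touched]]
        if (length(touched) > 0L) {
          dec <- tabulate(touched, nbins = n)
          deg <- deg - dec
        }
      }
      qk[as.character(k)] <- s
    } else {
      k <- k + 1L
    }
  }
  structure(list(
    shell = stats::setNames(shell, net$labels),
    stage = stats::setNames(stage, net$labels),
    stage_counts = qk,
    max_stage_count = if (length(qk)) max(qk) else 0L
  ), class = "shell_decomposition")
}

#' @export
print.shell_decomposition <- function(x, ...) {
  cat("shell_decomposition:", length(x$shell), "nodes, shells",
      paste(names(x$stage_counts), collapse = " "),
      "| max q(k) =", x$max_stage_count, "\n")
  invisible(x)
}

#' Improved k-shell index
#'
#' Adds to each node's shell value a fractional correction
#' p(i) / (max_k q(k) + 1), where p(i) is the removal stage of node i within
#' its shell and q(k) the number of stages of shell k. Nodes peeled later
#' within the same shell score higher; the correction is always in (0, 1) so
#' the integer part of the index remains the plain shell value.
#'
#' @param dec a `shell_decomposition`, or a `spread_network` (decomposed
#'   on the fly)
#' @return named numeric vector of improved k-shell values
#' @examples
#' round(improved_kshell(toy_network()), 4)  # node 3 -> 2.6667
#' @export
improved_kshell <- function(dec) {
  if (inherits(dec, "spread_network")) dec <- kshell_decompose(dec)
  stopifnot(inherits(dec, "shell_decomposition"))
  dec$shell + dec$stage / (dec$max_stage_count + 1)
}

#' Degree/k-shell (DK) index
#'
#' DK(i) = k(i) + k_s*(i): the node degree plus the improved k-shell index.
#' Combines local (degree) and global (core position, peeling stage)
#' information into a single high-resolution score, used as the node mass
#' in [dkgm()].
#'
#' @param net a `spread_network`
#' @param ks_star optional precomputed [improved_kshell()] vector covering
#'   all nodes; computed from `net` when missing
#' @return named numeric vector of DK values
#' @examples
#' round(dk_index(toy_network()), 4)
#' @export
dk_index <- function(net, ks_star = NULL) {
  stopifnot(inherits(net, "spread_network"))
  if (is.null(ks_star)) ks_star <- improved_kshell(net)
  if (!all(net$labels %in% names(ks_star)))
    stop("ks_star must cover every node of the network")
  degrees(net) + ks_star[net$labels]
}
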
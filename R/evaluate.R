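#' Kendall's tau with tied pairs excluded
#'
#' Counts concordant (n+) and discordant (n-) unordered index pairs of the
#' two sequences; a pair tied in either sequence counts as neither. Returns
#' \deqn{\tau = \frac{2(n_+ - n_-)}{N(N-1)}}
#' so heavy ties shrink |tau| towards 0 (the denominator always counts all
#' pairs). The tau-b variant, which rescales for ties, is available via
#' `variant = "b"` for comparison but is never used by the evaluation
#' harness.
#'
#' Scores are compared after rounding to 10 significant digits so that tie
#' classes are stable against floating-point accumulation order.
#'
#' @param x,y numeric sequences of equal length N >= 2
#' @param variant `"a"` (default, the definition above) or `"b"`
#' @return tau in \[-1, 1\]
#' @examples
#' kendall_tau(c(1, 1, 2), c(1, 2, 3))  # 2/3: one pair tied in x
#' @export
kendall_tau <- function(x, y, variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("sequences must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 elements")
  x <- signif(as.numeric(x), 10)
  y <- signif(as.numeric(y), 10)
  if (variant == "b") return(stats::cor(x, y, method = "kendall"))
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  sum(sx * sy) / (n * (n - 1))
}

#' Monotonicity of a ranking list
#'
#' Measures how completely a score vector resolves the nodes: with tie
#' classes of sizes N_t,
#' \deqn{M_r = \left[1 - \frac{\sum_t N_t (N_t - 1)}{N (N - 1)}\right]^2.}
#' 1 means all scores distinct, 0 means all tied. Scores are compared after
#' rounding to 10 significant digits.
#'
#' @param scores numeric vector of length N >= 2
#' @return monotonicity in \[0, 1\]
#' @examples
#' monotonicity(c(1, 3, 3, 4, 4, 4, 5, 1, 1))  # (58/72)^2
#' @export
monotonicity <- function(scores) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores")
  nt <- table(signif(as.numeric(scores), 10))
  (1 - sum(nt * (nt - 1)) / (n * (n - 1)))^2
}

#' Evaluate a method's scores against the SIR standard ranking
#'
#' Computes Kendall's tau between the method's scores and the simulated
#' influence F(i) (paired in the network's node order), and the
#' monotonicity of the method's scores.
#'
#' @param net a `spread_network`
#' @param scores named numeric score vector covering the network's nodes
#' @param standard a [sir_influence()] object on the same network
#' @param method_name label for the report
#' @return an object of class `evaluation_report`: list with `method`,
#'   `tau`, `monotonicity`, `beta`, `n`
#' @export
evaluate_method <- function(net, scores, standard, method_name = "method") {
  stopifnot(inherits(net, "spread_network"), inherits(standard, "sir_influence"))
  if (!setequal(names(scores), net$labels) ||
      !setequal(names(standard$influence), net$labels))
    stop("score and influence vectors must cover exactly the network's nodes")
  x <- as.numeric(scores[net$labels])
  y <- as.numeric(standard$influence[net$labels])
  structure(list(
    method = method_name,
    tau = kendall_tau(x, y),
    monotonicity = monotonicity(x),
    beta = standard$beta,
    n = net$n
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s: tau = %.4f, monotonicity = %.4f (beta = %.4g, N = %d)\n",
              x$method, x$tau, x$monotonicity, x$beta, x$n))
  invisible(x)
}

#' Benchmark several ranking methods against the SIR standard
#'
#' Runs the SIR simulation once, scores the network with each requested
#' method, and reports tau and monotonicity per method.
#'
#' @param net a `spread_network`
#' @param methods character vector of method names (see [score_method()])
#' @param beta infection probability, or `"auto"` for [epidemic_threshold()]
#' @param radius gravity truncation radius, or `NULL` for the per-method
#'   default
#' @param realizations SIR realizations (default 1000)
#' @param rng_seed optional seed for the simulation
#' @return a data.frame with columns `method`, `tau`, `monotonicity`,
#'   `beta`, `n`
#' @export
evaluate_methods <- function(net,
                             methods = c("dc", "ks", "hindex", "bc", "cc",
                                         "gc", "lgm", "dkgm"),
                             beta = "auto", radius = NULL,
                             realizations = 1000, rng_seed = NULL) {
  std <- sir_influence(net, beta = beta, realizations = realizations,
                       rng_seed = rng_seed)
  rows <- lapply(methods, function(m) {
    rep <- evaluate_method(net, score_method(net, m, radius = radius),
                           std, method_name = m)
    data.frame(method = m, tau = rep$tau, monotonicity = rep$monotonicity,
               beta = rep$beta, n = rep$n)
  })
  do.call(rbind, rows)
}
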
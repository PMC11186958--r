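#' Auxiliary-sampler configuration
#'
#' Controls the single-dyad toggle Metropolis-Hastings runs used to draw
#' (approximate) ERGM samples — both the auxiliary networks inside exchange
#' updates and posterior-predictive simulations.
#'
#' Initialisation conventions: exchange updates start the auxiliary chain at
#' the observed network (`"observed"`); posterior-predictive simulation uses
#' an Erdos-Renyi draw of matched density (`"random"`).
#'
#' @param n_aux number of toggle iterations (default 1000).
#' @param init one of `"observed"`, `"empty"`, `"random"`.
#' @param density edge density of the `"random"` initial graph.
#' @param rng_seed optional seed applied (via `set.seed`) before each
#'   simulation; leave `NULL` to use the ambient RNG stream.
#' @export
aux_config <- function(n_aux = 1000, init = c("observed", "empty", "random"),
                       density = 0.1, rng_seed = NULL) {
  init <- match.arg(init)
  n_aux <- as.integer(n_aux)
  if (is.na(n_aux) || n_aux < 1) stop("n_aux must be >= 1")
  structure(list(n_aux = n_aux, init = init, density = density,
                 rng_seed = rng_seed),
            class = "ergmpop_aux")
}

#' Unnormalised ERGM log-probability
#'
#' theta' s(y); the normalising constant Z(theta) is not computed.
#'
#' @param g an `ergmpop_graph`.
#' @param theta numeric p-vector.
#' @param spec an [ergm_spec()].
#' @export
log_unnorm <- function(g, theta, spec) {
  if (length(theta) != spec$p)
    stop("theta length does not match the number of terms")
  sum(theta * summary_stats(g, spec))
}

#' Exact log normalising constant by exhaustive enumeration
#'
#' Enumerates all `2^(N(N-1)/2)` graphs on the template's node set; a test
#' oracle, feasible only for `N <= 6`. Node attributes are taken from the
#' template.
#'
#' @param theta numeric p-vector.
#' @param spec an [ergm_spec()].
#' @param template an `ergmpop_graph` with `N <= 6` providing the node set
#'   and attributes.
#' @return `log Z(theta)`.
#' @export
exact_log_partition <- function(theta, spec, template) {
  stopifnot(is_ergmpop_graph(template))
  n <- template$n_nodes
  if (n > 6) stop("exact enumeration limited to N <= 6")
  if (length(theta) != spec$p) stop("theta length does not match term count")
  ut <- which(upper.tri(matrix(0, n, n)))
  nd <- length(ut)
  lp <- numeric(2^nd)
  g <- template
  for (code in 0:(2^nd - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(nd)])
    adj <- matrix(0L, n, n)
    adj[ut] <- bits
    adj <- adj + t(adj)
    g <- graph_with_adjacency(g, adj)
    lp[code + 1] <- sum(theta * summary_stats(g, spec))
  }
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

#' Enumerated ERGM probability mass function (test oracle)
#'
#' @inheritParams exact_log_partition
#' @return data.frame with one row per graph: `code` (bit pattern over dyads
#'   in column-major upper-triangle order) and `prob`.
#' @export
exact_pmf <- function(theta, spec, template) {
  n <- template$n_nodes
  if (n > 6) stop("exact enumeration limited to N <= 6")
  ut <- which(upper.tri(matrix(0, n, n)))
  nd <- length(ut)
  lp <- numeric(2^nd)
  g <- template
  for (code in 0:(2^nd - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(nd)])
    adj <- matrix(0L, n, n)
    adj[ut] <- bits
    adj <- adj + t(adj)
    g <- graph_with_adjacency(g, adj)
    lp[code + 1] <- sum(theta * summary_stats(g, spec))
  }
  m <- max(lp)
  p <- exp(lp - m); p <- p / sum(p)
  data.frame(code = 0:(2^nd - 1), prob = p)
}

# map a graph to its enumeration code (shared with exact_pmf)
graph_code <- function(g) {
  ut <- which(upper.tri(g$adjacency))
  sum(g$adjacency[ut] * 2^(seq_along(ut) - 1))
}

#' Simulate from an ERGM by toggle Metropolis-Hastings
#'
#' Runs `cfg$n_aux` single-dyad toggle updates — propose a uniformly random
#' dyad, accept the toggle with probability `min(1, exp(+/- theta' ds))` —
#' and returns the final state as an approximate draw from the ERGM. With a
#' fixed RNG state the result is deterministic.
#'
#' @param theta numeric p-vector.
#' @param spec an [ergm_spec()].
#' @param template an `ergmpop_graph` providing the node set, attributes, and
#'   (for `init = "observed"`) the starting adjacency.
#' @param cfg an [aux_config()].
#' @return an `ergmpop_graph`; the attribute `"stats"` carries its summary
#'   statistics.
#' @export
simulate_ergm <- function(theta, spec, template, cfg = aux_config()) {
  stopifnot(is_ergmpop_graph(template), inherits(spec, "ergmpop_spec"))
  if (length(theta) != spec$p) stop("theta length does not match term count")
  if (any(!is.finite(theta))) stop("theta must be finite")
  n <- template$n_nodes
  if (n > 60)
    warning("N > 60: fixed-length auxiliary runs may not reach the ERGM; ",
            "consider increasing n_aux", call. = FALSE)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  adj0 <- switch(cfg$init,
    observed = template$adjacency,
    empty = matrix(0L, n, n),
    random = {
      m <- matrix(0L, n, n)
      ut <- which(upper.tri(m))
      m[ut] <- as.integer(runif(length(ut)) < cfg$density)
      m + t(m)
    })
  nd <- spec_node_data(template, spec)
  res <- cpp_simulate_ergm(adj0, as.numeric(theta), cfg$n_aux,
                           term_codes(spec), nd$hemi, nd$partner,
                           spec$gwesp_decay)
  out <- graph_with_adjacency(template, res$adjacency)
  attr(out, "stats") <- setNames(as.numeric(res$stats), spec$terms)
  out
}
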
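#' Count the edges of a graph
#' @param g an `ergmpop_graph`.
#' @return non-negative integer.
#' @export
count_edges <- function(g) {
  stopifnot(is_ergmpop_graph(g))
  sum(g$adjacency) %/% 2L
}

#' Count edges whose endpoints share a node attribute
#'
#' @param g an `ergmpop_graph`.
#' @param attribute attribute name; currently `"hemisphere"`.
#' @return non-negative integer.
#' @export
count_nodematch <- function(g, attribute = "hemisphere") {
  stopifnot(is_ergmpop_graph(g))
  vals <- g[[attribute]]
  if (is.null(vals))
    stop("graph has no node attribute '", attribute, "'")
  same <- outer(vals, vals, "==")
  sum(g$adjacency[same]) %/% 2L
}

#' Count edges between homotopic node pairs
#' @param g an `ergmpop_graph` with a homotopy partner map.
#' @return non-negative integer.
#' @export
count_homotopy <- function(g) {
  stopifnot(is_ergmpop_graph(g))
  if (is.null(g$homotopy_partner))
    stop("graph has no homotopy partner map")
  sum(g$adjacency[cbind(seq_len(g$n_nodes), g$homotopy_partner)]) %/% 2L
}

#' Edgewise shared-partner counts
#'
#' `EP_w` counts the connected node pairs (edges) whose endpoints have exactly
#' `w` common neighbours, for `w = 0 .. N-2`. The counts sum to the number of
#' edges.
#'
#' @param g an `ergmpop_graph`.
#' @return named integer vector of length `N - 1` (names `"0"` .. `"N-2"`).
#' @export
esp_counts <- function(g) {
  stopifnot(is_ergmpop_graph(g))
  ep <- cpp_esp_counts(g$adjacency)
  setNames(ep, as.character(seq_along(ep) - 1L))
}

#' Geometrically weighted edgewise shared partners (GWESP)
#'
#' GWESP(y) = exp(tau) * sum_w \{1 - (1 - exp(-tau))^w\} EP_w(y), with the sum
#' over w = 1 .. N-2 (an edge with no shared partner contributes zero). The
#' decay tau attenuates the marginal effect of higher shared-partner counts.
#'
#' @param g an `ergmpop_graph`.
#' @param tau positive decay parameter.
#' @return non-negative real.
#' @examples
#' tri <- network_graph(1 - diag(3))
#' gwesp(tri, 0.9) # == 3 for any tau
#' @export
gwesp <- function(g, tau = 0.9) {
  stopifnot(is_ergmpop_graph(g))
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive number")
  ep <- cpp_esp_counts(g$adjacency)
  w <- seq_along(ep) - 1L
  exp(tau) * sum((1 - (1 - exp(-tau))^w) * ep)
}

#' Evaluate the ERGM summary-statistic vector
#'
#' @param g an `ergmpop_graph`.
#' @param spec an [ergm_spec()].
#' @return named numeric p-vector in the spec's term order.
#' @export
summary_stats <- function(g, spec) {
  stopifnot(is_ergmpop_graph(g), inherits(spec, "ergmpop_spec"))
  nd <- spec_node_data(g, spec)
  s <- cpp_summary_stats(g$adjacency, term_codes(spec), nd$hemi, nd$partner,
                         spec$gwesp_decay)
  setNames(as.numeric(s), spec$terms)
}

#' Change statistics for a single dyad
#'
#' Returns `s(y+) - s(y-)` where `y+` and `y-` are the graph with the dyad
#' set to 1 and 0 respectively — independent of the dyad's current state.
#' These local differences drive the toggle Metropolis-Hastings sampler.
#'
#' @param g an `ergmpop_graph`.
#' @param dyad integer pair `c(i, j)`, 1-based, `i != j`.
#' @param spec an [ergm_spec()].
#' @return named numeric p-vector.
#' @export
change_stats <- function(g, dyad, spec) {
  stopifnot(is_ergmpop_graph(g), inherits(spec, "ergmpop_spec"))
  dyad <- as.integer(dyad)
  if (length(dyad) != 2 || dyad[1] == dyad[2] ||
      any(dyad < 1L) || any(dyad > g$n_nodes))
    stop("dyad must be a pair of distinct node indices")
  adj <- g$adjacency
  i <- dyad[1]; j <- dyad[2]
  adj[i, j] <- 0L; adj[j, i] <- 0L
  nd <- spec_node_data(g, spec)
  d <- cpp_change_stats(adj, i - 1L, j - 1L, term_codes(spec), nd$hemi,
                        nd$partner, spec$gwesp_decay)
  setNames(as.numeric(d), spec$terms)
}

#' Network metric distributions for goodness-of-fit
#'
#' Computes the three metric distributions used by the posterior-predictive
#' assessment: the degree distribution (counts over degrees `0..N-1`), the
#' geodesic-distance distribution over unordered node pairs (counts over
#' `1..N-1` plus a distinct `Inf` bin for disconnected pairs; shortest paths
#' by breadth-first search) and the edgewise shared-partner distribution.
#'
#' @param g an `ergmpop_graph`.
#' @return list of class `ergmpop_metrics` with named count vectors `degree`,
#'   `geodesic`, `esp`.
#' @export
metric_distributions <- function(g) {
  stopifnot(is_ergmpop_graph(g))
  n <- g$n_nodes
  deg <- tabulate(rowSums(g$adjacency) + 1L, nbins = n)
  names(deg) <- as.character(0:(n - 1))

  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  dmat <- igraph::distances(ig)
  dv <- dmat[upper.tri(dmat)]
  geo <- tabulate(dv[is.finite(dv)], nbins = n - 1L)
  geo <- c(geo, sum(is.infinite(dv)))
  names(geo) <- c(as.character(1:(n - 1)), "Inf")

  structure(list(degree = deg, geodesic = geo, esp = esp_counts(g)),
            class = "ergmpop_metrics")
}
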
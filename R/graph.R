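#' Construct a network graph
#'
#' A graph is a binary undirected network on `N` labelled nodes, stored as a
#' symmetric 0/1 adjacency matrix with a zero diagonal, plus optional node
#' attributes: a hemisphere label per node and a homotopy partner map pairing
#' each node with its mirror node in the opposite hemisphere. The partner map
#' must be a fixed-point-free involution (`partner[partner[i]] == i`,
#' `partner[i] != i`).
#'
#' @param adjacency square numeric/integer matrix with entries in `{0, 1}`,
#'   symmetric, zero diagonal. Node names are taken from `rownames` if set.
#' @param hemisphere optional character/factor vector of per-node hemisphere
#'   labels (length `N`).
#' @param homotopy_partner optional integer vector, `homotopy_partner[i]` the
#'   1-based index of node `i`'s mirrored node.
#' @return an object of class `ergmpop_graph` with elements `n_nodes`,
#'   `adjacency`, `hemisphere`, `homotopy_partner`.
#' @examples
#' g <- network_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' count_edges(g)
#' @export
network_graph <- function(adjacency, hemisphere = NULL, homotopy_partner = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  n <- nrow(adjacency)
  storage.mode(adjacency) <- "integer"
  if (any(is.na(adjacency)) || !all(adjacency %in% c(0L, 1L)))
    stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all(adjacency == t(adjacency))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0L))
    stop("adjacency must have a zero diagonal")
  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != n)
      stop("hemisphere must have one label per node")
  }
  if (!is.null(homotopy_partner)) {
    homotopy_partner <- as.integer(homotopy_partner)
    if (length(homotopy_partner) != n)
      stop("homotopy_partner must have one entry per node")
    if (any(is.na(homotopy_partner)) ||
        any(homotopy_partner < 1L) || any(homotopy_partner > n))
      stop("homotopy_partner indices out of range")
    if (any(homotopy_partner == seq_len(n)))
      stop("homotopy_partner must be fixed-point free")
    if (any(homotopy_partner[homotopy_partner] != seq_len(n)))
      stop("homotopy_partner must be an involution")
  }
  structure(
    list(n_nodes = n, adjacency = adjacency, hemisphere = hemisphere,
         homotopy_partner = homotopy_partner),
    class = "ergmpop_graph"
  )
}

#' @export
print.ergmpop_graph <- function(x, ...) {
  cat(sprintf("ergmpop graph: %d nodes, %d edges", x$n_nodes, count_edges(x)))
  if (!is.null(x$hemisphere))
    cat(sprintf(", hemispheres: %s", paste(unique(x$hemisphere), collapse = "/")))
  if (!is.null(x$homotopy_partner)) cat(", homotopy map present")
  cat("\n")
  invisible(x)
}

is_ergmpop_graph <- function(x) inherits(x, "ergmpop_graph")

#' Replace the adjacency of a graph, keeping node attributes
#' @noRd
graph_with_adjacency <- function(g, adjacency) {
  storage.mode(adjacency) <- "integer"
  g$adjacency <- adjacency
  g
}

# --- readers / writers ------------------------------------------------------

#' Read and write adjacency matrices as CSV/TSV
#'
#' The on-disk format is an `N x N` 0/1 matrix, optionally with a header row
#' of node names. `read_adjacency()` infers the separator from the file
#' extension (`.tsv` uses tabs).
#'
#' @param path file path.
#' @param header does the file carry a header row of node names?
#' @param hemisphere,homotopy_partner node attributes passed to
#'   [network_graph()].
#' @return `read_adjacency()` returns an `ergmpop_graph`.
#' @export
read_adjacency <- function(path, header = FALSE, hemisphere = NULL,
                           homotopy_partner = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  m <- as.matrix(read.csv(path, header = header, sep = sep))
  dimnames(m) <- NULL
  network_graph(m, hemisphere = hemisphere, homotopy_partner = homotopy_partner)
}

#' @rdname read_adjacency
#' @param g an `ergmpop_graph`.
#' @export
write_adjacency <- function(g, path) {
  stopifnot(is_ergmpop_graph(g))
  write.table(g$adjacency, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a graph from an edge list
#'
#' @param path two-column file (from, to), no header by default.
#' @param n_nodes total number of nodes (isolated nodes carry no edges).
#' @param one_based are node indices 1-based (`TRUE`, default) or 0-based?
#' @inheritParams read_adjacency
#' @export
read_edge_list <- function(path, n_nodes, one_based = TRUE, header = FALSE,
                           hemisphere = NULL, homotopy_partner = NULL) {
  el <- read.csv(path, header = header)
  m <- matrix(0L, n_nodes, n_nodes)
  if (nrow(el) > 0) {
    a <- as.integer(el[[1]]) + if (one_based) 0L else 1L
    b <- as.integer(el[[2]]) + if (one_based) 0L else 1L
    if (any(a < 1L | a > n_nodes | b < 1L | b > n_nodes))
      stop("edge list indices out of range")
    m[cbind(a, b)] <- 1L
    m[cbind(b, a)] <- 1L
  }
  diag(m) <- 0L
  network_graph(m, hemisphere = hemisphere, homotopy_partner = homotopy_partner)
}

#' Read a graph from GraphML
#'
#' Absent edges default to 0; the GraphML is read with \pkg{igraph} and
#' coerced to an undirected simple graph.
#' @inheritParams read_edge_list
#' @export
read_graphml <- function(path, hemisphere = NULL, homotopy_partner = NULL) {
  ig <- igraph::read_graph(path, format = "graphml")
  ig <- igraph::as_undirected(igraph::simplify(ig), mode = "collapse")
  m <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
  m[m > 1] <- 1
  dimnames(m) <- NULL
  network_graph(m, hemisphere = hemisphere, homotopy_partner = homotopy_partner)
}

#' Read a node-attribute table
#'
#' CSV with columns `node`, `hemisphere` and optionally `homotopy_partner`
#' (1-based). Rows may appear in any order; they are sorted by `node`.
#'
#' @param path file path.
#' @return list with elements `hemisphere` and `homotopy_partner`.
#' @export
read_node_attributes <- function(path) {
  tab <- read.csv(path)
  if (!all(c("node", "hemisphere") %in% names(tab)))
    stop("attribute table needs columns 'node' and 'hemisphere'")
  tab <- tab[order(tab$node), , drop = FALSE]
  list(
    hemisphere = as.character(tab$hemisphere),
    homotopy_partner = if ("homotopy_partner" %in% names(tab))
      as.integer(tab$homotopy_partner) else NULL
  )
}
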
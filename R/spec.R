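ERGM_TERMS <- c("edges", "nodematch.hemisphere", "nodematch.homotopy", "gwesp")

#' Specify the ERGM summary statistics
#'
#' An `ergm_spec` fixes the ordered set of summary statistics s(y) defining
#' the model; the order defines the coordinate order of every parameter
#' vector theta. Available terms:
#' \describe{
#'   \item{`edges`}{total number of edges}
#'   \item{`nodematch.hemisphere`}{edges whose endpoints share a hemisphere}
#'   \item{`nodematch.homotopy`}{edges joining homotopic (mirror) node pairs}
#'   \item{`gwesp`}{geometrically weighted edgewise shared partners with
#'     fixed decay `gwesp_decay` (the decay is never estimated)}
#' }
#' The natural parameter map is the identity: the log-probability is linear
#' in theta. Curved families are out of scope.
#'
#' @param terms character vector, a subset of
#'   `c("edges", "nodematch.hemisphere", "nodematch.homotopy", "gwesp")`,
#'   in the desired coordinate order.
#' @param gwesp_decay positive decay parameter tau of the gwesp term
#'   (default 0.9).
#' @return object of class `ergmpop_spec` with fields `terms`, `p`,
#'   `gwesp_decay`.
#' @examples
#' spec <- ergm_spec(c("edges", "nodematch.hemisphere", "gwesp"))
#' spec$p
#' @export
ergm_spec <- function(terms = c("edges", "nodematch.hemisphere", "gwesp"),
                      gwesp_decay = 0.9) {
  terms <- as.character(terms)
  if (length(terms) < 1) stop("at least one term required")
  bad <- setdiff(terms, ERGM_TERMS)
  if (length(bad))
    stop("unknown term(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(terms)) stop("duplicated terms")
  if ("gwesp" %in% terms) {
    if (!is.numeric(gwesp_decay) || length(gwesp_decay) != 1 ||
        !is.finite(gwesp_decay) || gwesp_decay <= 0)
      stop("gwesp_decay must be a positive number")
  }
  structure(
    list(terms = terms, p = length(terms), gwesp_decay = gwesp_decay),
    class = "ergmpop_spec"
  )
}

#' @export
print.ergmpop_spec <- function(x, ...) {
  lab <- x$terms
  lab[lab == "gwesp"] <- sprintf("gwesp(%g)", x$gwesp_decay)
  cat("ERGM statistics:", paste(lab, collapse = " + "), "\n")
  invisible(x)
}

# Integer codes shared with src/ergm_core.cpp.
term_codes <- function(spec) {
  match(spec$terms, ERGM_TERMS)
}

# Per-node vectors in the 0-based form the C++ core expects; validates that
# the graph carries the attributes the spec needs.
spec_node_data <- function(g, spec) {
  n <- g$n_nodes
  hemi <- rep(0L, n)
  partner <- rep(-1L, n)
  if ("nodematch.hemisphere" %in% spec$terms) {
    if (is.null(g$hemisphere))
      stop("spec includes nodematch.hemisphere but the graph has no hemisphere labels")
    hemi <- as.integer(factor(g$hemisphere))
  }
  if ("nodematch.homotopy" %in% spec$terms) {
    if (is.null(g$homotopy_partner))
      stop("spec includes nodematch.homotopy but the graph has no homotopy partner map")
    partner <- g$homotopy_partner - 1L
  }
  list(hemi = hemi, partner = partner)
}
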
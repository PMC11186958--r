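#' Template graph with two hemispheres and homotopic pairs
#'
#' Builds an empty graph on `n_nodes` nodes (even) split into left/right
#' hemispheres of equal size, with node `j` of the left hemisphere paired
#' with node `j + n_nodes/2` as its homotopic mirror.
#'
#' @param n_nodes even number of nodes (default 30).
#' @export
hemisphere_template <- function(n_nodes = 30) {
  if (n_nodes %% 2 != 0) stop("n_nodes must be even for two hemispheres")
  half <- n_nodes / 2
  network_graph(matrix(0L, n_nodes, n_nodes),
                hemisphere = rep(c("L", "R"), each = half),
                homotopy_partner = c(seq_len(half) + half, seq_len(half)))
}

#' Simulation designs for synthetic network populations
#'
#' Encodes the three reference simulation settings on 30-node two-hemisphere
#' graphs with the 3-term model (edges, nodematch.hemisphere, gwesp with
#' decay 0.9):
#' \describe{
#'   \item{`no_covariate`}{theta_i ~ N(mu, Sigma) with
#'     `mu = (-3, 0.5, 0.5)` and intercept-only design.}
#'   \item{`continuous`}{means uniformly spaced from `b = (-2.6, 0.5, 0.2)`
#'     (covariate 0) to `a = (-3, 0.5, 0.5)` (covariate 1):
#'     `mu_i = b + ((i-1)/(n-1)) (a - b)`, design rows
#'     `(1, (i-1)/(n-1))`, so the true coefficient rows are `(b, a - b)`.}
#'   \item{`binary`}{two groups of `n` networks each with means
#'     `mu1 = a`, `mu2 = b` and a one-hot two-column design, so the true
#'     coefficient rows are `(a, b)`.}
#' }
#' In all settings `Sigma` is the stated covariance `(1/50) [[1, -0.5, 0],
#' [-0.5, 0.5, 0], [0, 0, 0.5]]`.
#'
#' @param setting one of `"no_covariate"`, `"continuous"`, `"binary"`.
#' @param n number of networks (per group, for `"binary"`).
#' @param n_nodes nodes per network (default 30, even).
#' @param spec statistic specification (default: the 3-term model).
#' @param mu,a,b,Sigma generative truth; defaults as above.
#' @param rng_seed optional seed for [generate_population()].
#' @param sim_aux an [aux_config()] for network generation; the default runs
#'   40 toggle sweeps over the dyads from a sparse random start, long enough
#'   for these sparse, weakly clustered models.
#' @export
simulation_design <- function(setting = c("no_covariate", "continuous",
                                          "binary"),
                              n = 10, n_nodes = 30,
                              spec = ergm_spec(), mu = c(-3, 0.5, 0.5),
                              a = c(-3, 0.5, 0.5), b = c(-2.6, 0.5, 0.2),
                              Sigma = matrix(c(1, -0.5, 0, -0.5, 0.5, 0,
                                               0, 0, 0.5), 3, 3) / 50,
                              rng_seed = NULL, sim_aux = NULL) {
  setting <- match.arg(setting)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != spec$p || ncol(Sigma) != spec$p)
    stop("Sigma must be p x p for the chosen spec")
  if (inherits(tryCatch(chol(Sigma), error = identity), "error"))
    stop("Sigma must be positive definite")
  if (is.null(sim_aux))
    sim_aux <- aux_config(n_aux = 40 * choose(n_nodes, 2), init = "random",
                          density = 0.1)
  structure(list(setting = setting, n = as.integer(n),
                 n_nodes = as.integer(n_nodes), spec = spec, mu = mu,
                 a = a, b = b, Sigma = Sigma, rng_seed = rng_seed,
                 sim_aux = sim_aux),
            class = "ergmpop_design")
}

#' Generate a synthetic population of networks
#'
#' Draws per-network parameters from the design's Gaussian truth, simulates
#' each network with a long toggle Metropolis-Hastings run, and attaches the
#' design-appropriate covariate matrix.
#'
#' @param design an [simulation_design()].
#' @return list with `data` (an [population_data()]) and `truth` (the
#'   generative `beta_true`, `theta_true`, means and covariance).
#' @export
generate_population <- function(design) {
  stopifnot(inherits(design, "ergmpop_design"))
  if (!is.null(design$rng_seed)) set.seed(design$rng_seed)
  p <- design$spec$p
  n <- design$n

  gen <- switch(design$setting,
    no_covariate = {
      X <- matrix(1, n, 1)
      mus <- matrix(design$mu, n, p, byrow = TRUE)
      list(X = X, mus = mus, beta_true = matrix(design$mu, 1, p))
    },
    continuous = {
      xv <- (seq_len(n) - 1) / (n - 1)
      X <- cbind(1, xv)
      mus <- matrix(design$b, n, p, byrow = TRUE) +
        outer(xv, design$a - design$b)
      list(X = X, mus = mus, beta_true = rbind(design$b,
                                               design$a - design$b))
    },
    binary = {
      X <- rbind(matrix(c(1, 0), n, 2, byrow = TRUE),
                 matrix(c(0, 1), n, 2, byrow = TRUE))
      mus <- rbind(matrix(design$a, n, p, byrow = TRUE),
                   matrix(design$b, n, p, byrow = TRUE))
      list(X = X, mus = mus, beta_true = rbind(design$a, design$b))
    })

  n_total <- nrow(gen$X)
  ch <- chol(design$Sigma)
  theta_true <- gen$mus + matrix(rnorm(n_total * p), n_total, p) %*% ch
  template <- hemisphere_template(design$n_nodes)
  networks <- vector("list", n_total)
  for (i in seq_len(n_total))
    networks[[i]] <- simulate_ergm(theta_true[i, ], design$spec, template,
                                   design$sim_aux)
  list(
    data = population_data(networks, gen$X, design$spec),
    truth = list(beta_true = gen$beta_true, theta_true = theta_true,
                 mus = gen$mus, Sigma = design$Sigma,
                 setting = design$setting)
  )
}

# --- correlation-matrix front end ------------------------------------------

#' Threshold a correlation matrix into a binary network
#'
#' An edge joins nodes k and l iff `C[k, l] >= r` (off-diagonal only).
#'
#' @param C symmetric correlation matrix with unit diagonal.
#' @param r threshold in `[-1, 1]` (values outside give complete/empty
#'   graphs).
#' @param hemisphere,homotopy_partner optional node attributes.
#' @return an `ergmpop_graph`.
#' @export
threshold_correlation <- function(C, r, hemisphere = NULL,
                                  homotopy_partner = NULL) {
  C <- as.matrix(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("C must be symmetric")
  adj <- (C >= r) * 1L
  diag(adj) <- 0L
  adj[adj != t(adj)] <- 0L   # guard against asymmetric rounding at ties
  network_graph(adj, hemisphere = hemisphere,
                homotopy_partner = homotopy_partner)
}

#' Degree-targeted threshold selection
#'
#' Chooses the threshold r so that the mean node degree across all
#' thresholded networks is the largest achievable value not exceeding
#' `target_degree` (the mean degree is a decreasing step function of r; the
#' search scans the sorted off-diagonal values). Deterministic.
#'
#' @param Cs list of correlation matrices on a common node set.
#' @param target_degree desired average node degree (default 3).
#' @return the selected threshold r.
#' @export
find_threshold <- function(Cs, target_degree = 3) {
  if (!length(Cs)) stop("need at least one correlation matrix")
  N <- nrow(Cs[[1]])
  vals <- unlist(lapply(Cs, function(C) C[upper.tri(C)]))
  n_total <- length(Cs) * N
  # mean degree at threshold r: 2 * #{values >= r} / (n * N); a step
  # function of r, decreasing in r, so scan the sorted candidate values
  # max(vals) + 1 yields the empty graphs, so degree 0 is always reachable
  cand <- c(max(vals) + 1, sort(unique(vals), decreasing = TRUE))
  degs <- 2 * vapply(cand, function(r) sum(vals >= r), 0L) / n_total
  ok <- degs <= target_degree
  if (!any(ok)) {
    warning("target degree unreachable; returning the nearest achievable",
            call. = FALSE)
    return(cand[which.min(abs(degs - target_degree))])
  }
  best <- which(ok)[which.max(degs[ok])]
  cand[best]
}

#' Generate synthetic correlation matrices (factor model)
#'
#' A stand-in for functional-connectivity correlation matrices: each
#' subject's covariance is `A_i A_i' + d I` with `A_i = L + noise * Z_i`,
#' where `L` holds shared factor loadings (optionally block-structured) and
#' `Z_i` is subject-specific Gaussian noise; the covariance is standardised
#' to a correlation matrix. `noise = 0` gives identical subjects. Output is
#' synthetic and makes no claim to reproduce real fMRI dependence structure.
#'
#' @param n number of subjects.
#' @param n_nodes nodes (regions) per matrix.
#' @param n_factors number of shared factors (default 2).
#' @param block_sizes optional integer vector partitioning the nodes into
#'   communities, one factor per block (overrides `n_factors`).
#' @param noise subject-level loading noise (default 0.2).
#' @param loading strength of the shared loadings (default 0.8).
#' @param rng_seed optional seed.
#' @return list of `n` correlation matrices.
#' @export
generate_correlation_population <- function(n, n_nodes, n_factors = 2,
                                            block_sizes = NULL, noise = 0.2,
                                            loading = 0.8, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (!is.null(block_sizes)) {
    if (sum(block_sizes) != n_nodes) stop("block_sizes must sum to n_nodes")
    n_factors <- length(block_sizes)
    L <- matrix(0, n_nodes, n_factors)
    idx <- rep(seq_along(block_sizes), block_sizes)
    L[cbind(seq_len(n_nodes), idx)] <- loading
  } else {
    L <- matrix(rnorm(n_nodes * n_factors, sd = loading), n_nodes, n_factors)
  }
  lapply(seq_len(n), function(i) {
    A <- L + noise * matrix(rnorm(n_nodes * n_factors), n_nodes, n_factors)
    S <- A %*% t(A) + diag(n_nodes) * 0.5
    C <- stats::cov2cor(S)
    (C + t(C)) / 2
  })
}
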
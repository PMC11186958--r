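# Small graphs and independent (non-package) oracles used across tests.

complete_graph <- function(n, ...) network_graph(1 - diag(n), ...)

path_graph <- function(n, ...) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- 1L
  network_graph(m, ...)
}

edge_graph <- function(n, edges, ...) {
  m <- matrix(0L, n, n)
  for (e in edges) { m[e[1], e[2]] <- 1L; m[e[2], e[1]] <- 1L }
  network_graph(m, ...)
}

random_graph <- function(n, density = 0.4, ...) {
  m <- matrix(0L, n, n)
  ut <- which(upper.tri(m))
  m[ut] <- rbinom(length(ut), 1, density)
  network_graph(m + t(m), ...)
}

# attributes for a 4-node two-hemisphere fixture with mirror pairs 1-3, 2-4
hemi4 <- rep(c("L", "R"), each = 2)
partner4 <- c(3L, 4L, 1L, 2L)

# --- brute-force oracles (plain R, independent of the compiled path) -------

r_esp_counts <- function(adj) {
  n <- nrow(adj)
  ep <- integer(max(n - 1, 1))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!adj[i, j]) next
    w <- sum(adj[i, ] == 1 & adj[j, ] == 1)
    ep[w + 1] <- ep[w + 1] + 1L
  }
  ep
}

r_gwesp <- function(adj, tau) {
  ep <- r_esp_counts(adj)
  w <- seq_along(ep) - 1
  exp(tau) * sum((1 - (1 - exp(-tau))^w) * ep)
}

# enumerate all graphs on n nodes; f(adjacency) is accumulated
enumerate_graphs <- function(n, f) {
  ut <- which(upper.tri(matrix(0, n, n)))
  vapply(0:(2^length(ut) - 1), function(code) {
    adj <- matrix(0L, n, n)
    adj[ut] <- as.integer(intToBits(code)[seq_along(ut)])
    f(adj + t(adj))
  }, numeric(1))
}

# enumeration code matching exact_pmf(): bits over the upper triangle in
# column-major order
adjacency_code <- function(adj) {
  ut <- which(upper.tri(adj))
  sum(adj[ut] * 2^(seq_along(ut) - 1))
}

# quadrature posterior CDF for a single-network edges-only model with a
# N(mu0, v0) prior: p(theta | y) propto exp(theta * s) (1 + e^theta)^-ndyads
quadrature_edges_posterior <- function(s_obs, n_dyads, mu0 = 0, v0 = 100,
                                       lo = -8, hi = 6, m = 8001) {
  grid <- seq(lo, hi, length.out = m)
  lp <- grid * s_obs - n_dyads * log1p(exp(grid)) - (grid - mu0)^2 / (2 * v0)
  w <- exp(lp - max(lp))
  cdf <- cumsum(w) / sum(w)
  list(grid = grid, cdf = cdf,
       mean = sum(grid * w) / sum(w),
       sd = sqrt(sum(grid^2 * w) / sum(w) - (sum(grid * w) / sum(w))^2))
}

# batch-means Monte Carlo standard error
mcse <- function(x, batches = 20) {
  bm <- tapply(x, cut(seq_along(x), batches, labels = FALSE), mean)
  sd(bm) / sqrt(batches)
}
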
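#' Goodness-of-fit configuration
#'
#' @param S number of posterior draws used for predictive simulation
#'   (default 100).
#' @param band pointwise credible-band level (default 0.90).
#' @param rng_seed optional seed.
#' @param include_residual also draw a residual from `Sigma_eps` per
#'   predictive network, rather than simulating at the mean `x' beta` only?
#'   Off by default; turning it on makes the check dispersion-aware.
#' @export
gof_config <- function(S = 100, band = 0.90, rng_seed = NULL,
                       include_residual = FALSE) {
  stopifnot(S >= 1, band > 0, band < 1)
  structure(list(S = as.integer(S), band = band, rng_seed = rng_seed,
                 include_residual = include_residual),
            class = "ergmpop_gof_config")
}

#' Simulate posterior-predictive networks
#'
#' Chooses `S` posterior draws of beta uniformly at random and, for each
#' draw, simulates one network per distinct design row at the mean parameter
#' `x' beta(s)` (plus, optionally, a residual draw from that iteration's
#' `Sigma_eps`). Auxiliary chains start from an Erdos-Renyi graph whose
#' density matches the template's.
#'
#' @param fit an `ergmpop_fit`.
#' @param template an `ergmpop_graph` providing the node set and attributes.
#' @param cfg a [gof_config()].
#' @param aux an [aux_config()]; `init` is forced to `"random"`.
#' @param X design matrix whose distinct rows define the predictive groups
#'   (default: the fitted design).
#' @return list of `ergmpop_graph`s; each carries attributes `draw` (posterior
#'   draw index) and `group` (distinct-row label).
#' @export
posterior_predictive <- function(fit, template, cfg = gof_config(),
                                 aux = aux_config(), X = fit$X) {
  stopifnot(inherits(fit, "ergmpop_fit"))
  if (fit$n_kept < 1) stop("fit contains no posterior draws")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  X <- as.matrix(X)
  rows <- unique(X)
  groups <- apply(rows, 1, paste, collapse = ",")
  aux$init <- "random"
  aux$density <- count_edges(template) / choose(template$n_nodes, 2)
  aux$rng_seed <- NULL
  idx <- sample.int(fit$n_kept, cfg$S, replace = TRUE)
  out <- vector("list", cfg$S * nrow(rows))
  k <- 0L
  for (s in seq_len(cfg$S)) {
    beta_s <- matrix(fit$beta[idx[s], , ], fit$q, fit$p)
    for (r in seq_len(nrow(rows))) {
      theta <- drop(rows[r, , drop = FALSE] %*% beta_s)
      if (cfg$include_residual) {
        Sig <- matrix(fit$sigma_eps[idx[s], , ], fit$p, fit$p)
        theta <- theta + drop(rnorm(fit$p) %*% chol(Sig))
      }
      g <- simulate_ergm(theta, fit$spec, template, aux)
      attr(g, "draw") <- idx[s]
      attr(g, "group") <- groups[r]
      k <- k + 1L
      out[[k]] <- g
    }
  }
  out
}

#' Summarise observed vs posterior-predictive metric distributions
#'
#' For each metric (degree, geodesic distance, edgewise shared partners) and
#' each group (distinct design row), computes the observed per-network
#' counts and pointwise lower/upper quantile bands over the predictive
#' networks.
#'
#' @param observed list of `ergmpop_graph`s; `observed_groups` assigns each to
#'   a group (default: one group).
#' @param predictive output of [posterior_predictive()].
#' @param cfg a [gof_config()] (supplies the band level).
#' @param observed_groups character vector, one label per observed network.
#' @return data.frame of class `ergmpop_gof` in long format: `metric`,
#'   `group`, `abscissa`, `observed_median`, `lower`, `upper`.
#' @export
gof_summary <- function(observed, predictive, cfg = gof_config(),
                        observed_groups = NULL) {
  if (!length(observed) || !length(predictive))
    stop("observed and predictive network lists must be non-empty")
  if (is.null(observed_groups))
    observed_groups <- rep(attr(predictive[[1]], "group") %||% "all",
                           length(observed))
  pred_groups <- vapply(predictive, function(g) attr(g, "group"), "")
  a <- (1 - cfg$band) / 2

  metrics_of <- function(gs) lapply(gs, metric_distributions)
  obs_m <- metrics_of(observed)
  pred_m <- metrics_of(predictive)

  rows <- list()
  for (metric in c("degree", "geodesic", "esp")) {
    for (grp in unique(observed_groups)) {
      om <- do.call(rbind, lapply(obs_m[observed_groups == grp],
                                  `[[`, metric))
      sel <- pred_groups == grp
      pm <- if (any(sel))
        do.call(rbind, lapply(pred_m[sel], `[[`, metric)) else om * NA
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, group = grp, abscissa = colnames(om),
        observed_median = apply(om, 2, stats::median),
        lower = apply(pm, 2, quantile, probs = a, na.rm = TRUE),
        upper = apply(pm, 2, quantile, probs = 1 - a, na.rm = TRUE),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ergmpop_gof", "data.frame")
  attr(out, "band") <- cfg$band
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a goodness-of-fit summary
#'
#' One panel per metric: observed medians as points/lines over the
#' predictive credible ribbon. Requires \pkg{ggplot2}.
#'
#' @param x an `ergmpop_gof` data.frame.
#' @param ... unused.
#' @export
plot.ergmpop_gof <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  x$abscissa <- factor(x$abscissa, levels = unique(x$abscissa))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$abscissa, group = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$group), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed_median,
                                    colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_median,
                                     colour = .data$group), size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "count",
                  title = sprintf("Posterior predictive check (%d%% bands)",
                                  round(100 * attr(x, "band")))) +
    ggplot2::theme_minimal()
}
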
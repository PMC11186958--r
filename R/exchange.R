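#' Gaussian prior for an ERGM parameter vector
#'
#' In the multilevel model, network i's parameter has the conditional prior
#' N(x_i' beta, Sigma_eps); a single-network fit typically uses a flat
#' N(0, 100 I).
#'
#' @param mean numeric p-vector.
#' @param covariance p x p symmetric positive-definite matrix.
#' @export
gaussian_prior <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != length(mean) || ncol(covariance) != length(mean))
    stop("dimension mismatch between mean and covariance")
  if (!isTRUE(all.equal(covariance, t(covariance))))
    stop("covariance must be symmetric")
  ch <- tryCatch(chol(covariance), error = function(e)
    stop("covariance must be positive definite"))
  structure(list(mean = mean, covariance = covariance, chol = ch),
            class = "ergmpop_gaussian")
}

# log N(x; prior) up to a constant shared across evaluations
gaussian_logdens <- function(x, prior) {
  z <- backsolve(prior$chol, x - prior$mean, transpose = TRUE)
  -0.5 * sum(z^2)
}

#' Log acceptance ratio of the exchange update
#'
#' The auxiliary network y', drawn at the proposed theta', makes the
#' intractable normalising constants cancel, leaving
#' `(theta' - theta)' (s(y) - s(y')) + log pi(theta') - log pi(theta)`
#' with pi the Gaussian prior. The symmetric proposal density drops out.
#'
#' @param theta,theta_prime numeric p-vectors (current, proposed).
#' @param s_y,s_yprime summary statistics of the observed and auxiliary
#'   networks.
#' @param prior a [gaussian_prior()].
#' @return finite real.
#' @export
log_exchange_ratio <- function(theta, theta_prime, s_y, s_yprime, prior) {
  p <- length(prior$mean)
  if (length(theta) != p || length(theta_prime) != p ||
      length(s_y) != p || length(s_yprime) != p)
    stop("dimension mismatch")
  sum((theta_prime - theta) * (s_y - s_yprime)) +
    gaussian_logdens(theta_prime, prior) - gaussian_logdens(theta, prior)
}

#' One exchange-algorithm update of a single parameter vector
#'
#' Proposes theta' from the adaptive mixture proposal, simulates an auxiliary
#' network y' from the ERGM at theta' (auxiliary chain initialised at the
#' observed network), and accepts with probability
#' `min(1, exp(log_exchange_ratio))`.
#'
#' @param theta current numeric p-vector.
#' @param y observed `ergmpop_graph`.
#' @param spec an [ergm_spec()].
#' @param prior a [gaussian_prior()] on theta.
#' @param prop a [proposal_state()].
#' @param aux an [aux_config()]; `init` is forced to `"observed"`.
#' @param s_y optional precomputed `summary_stats(y, spec)`.
#' @return list with `theta` (new value), `accepted` (logical), and
#'   `s_aux` (auxiliary-network statistics, for diagnostics).
#' @export
exchange_update <- function(theta, y, spec, prior, prop, aux = aux_config(),
                            s_y = NULL) {
  if (is.null(s_y)) s_y <- summary_stats(y, spec)
  theta_prime <- propose(theta, prop)
  aux$init <- "observed"
  aux$rng_seed <- NULL
  y_prime <- simulate_ergm(theta_prime, spec, y, aux)
  s_yprime <- attr(y_prime, "stats")
  lr <- log_exchange_ratio(theta, theta_prime, s_y, s_yprime, prior)
  if (lr >= 0 || log(runif(1)) < lr) {
    list(theta = theta_prime, accepted = TRUE, s_aux = s_yprime)
  } else {
    list(theta = theta, accepted = FALSE, s_aux = s_yprime)
  }
}

#' Log acceptance ratio of the non-centred beta exchange update
#'
#' Under the non-centred parameterisation the regression coefficients beta
#' enter every network's likelihood through theta_i = x_i' beta + eps_i, so
#' the update needs one auxiliary network per observed network (each
#' simulated at x_i' beta' + eps_i). The normalising constants cancel
#' network-by-network, leaving
#' `sum_i (x_i'(beta' - beta))' (s(y_i) - s(y_i'))` plus the matrix-normal
#' prior log-ratio of beta conditional on Sigma_eps.
#'
#' @param beta,beta_prime q x p matrices (current, proposed).
#' @param X n x q design matrix.
#' @param s_obs,s_aux n x p matrices of summary statistics of the observed
#'   and auxiliary networks (or lists of p-vectors).
#' @param prior_on_beta list with `beta0` (q x p), `lambda0` (q x q) and
#'   `sigma_eps` (p x p), the conditional matrix-normal prior
#'   MN(beta0, lambda0^-1, sigma_eps).
#' @return finite real.
#' @export
ncp_beta_log_ratio <- function(beta, beta_prime, X, s_obs, s_aux,
                               prior_on_beta) {
  X <- as.matrix(X)
  if (is.list(s_obs)) s_obs <- do.call(rbind, s_obs)
  if (is.list(s_aux)) s_aux <- do.call(rbind, s_aux)
  n <- nrow(X)
  if (nrow(s_obs) != n || nrow(s_aux) != n)
    stop("need one observed and one auxiliary statistic vector per network")
  dmu <- X %*% (beta_prime - beta)            # n x p
  ll <- sum(dmu * (s_obs - s_aux))
  Sinv <- chol2inv(chol(prior_on_beta$sigma_eps))
  qf <- function(b) {
    r <- b - prior_on_beta$beta0
    sum(diag(Sinv %*% t(r) %*% prior_on_beta$lambda0 %*% r))
  }
  ll - 0.5 * (qf(beta_prime) - qf(beta))
}
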
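#' Bundle a population of networks with its design matrix
#'
#' @param networks list of `ergmpop_graph`s on a common node set (equal `N`
#'   and node attributes).
#' @param X n x q numeric design matrix, one row per network (row i is
#'   x_i'). An intercept-only model uses a single column of ones.
#' @param spec an [ergm_spec()].
#' @return object of class `ergmpop_population`.
#' @export
population_data <- function(networks, X, spec) {
  if (!length(networks) || !all(vapply(networks, is_ergmpop_graph, TRUE)))
    stop("networks must be a non-empty list of ergmpop_graph objects")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(networks))
    stop("X must have one row per network")
  ns <- vapply(networks, function(g) g$n_nodes, 1L)
  if (length(unique(ns)) != 1)
    stop("all networks must share the same node set")
  if (qr(X)$rank < ncol(X))
    warning("design matrix is column-rank deficient", call. = FALSE)
  structure(list(networks = networks, X = X, spec = spec,
                 n = length(networks), q = ncol(X), p = spec$p),
            class = "ergmpop_population")
}

#' Default prior hyperparameters
#'
#' The conditional conjugate prior is `beta | Sigma_eps ~ MN(beta0,
#' lambda0^-1, Sigma_eps)` and `Sigma_eps ~ InvWishart(V0, nu0)`. Defaults
#' are weakly informative: `beta0 = 0`, `lambda0^-1 = 100 I_q` (flat
#' regression coefficients), `V0 = I_p`, `nu0 = p + 1` (the smallest integer
#' degrees of freedom giving a proper inverse-Wishart on p x p matrices).
#'
#' @param p number of ERGM statistics.
#' @param q number of network-level covariates.
#' @return list of class `ergmpop_prior` with `beta0` (q x p), `lambda0`
#'   (q x q), `V0` (p x p), `nu0`.
#' @export
default_prior <- function(p, q) {
  stopifnot(p >= 1, q >= 1)
  prior_hyper(beta0 = matrix(0, q, p), lambda0 = diag(q) / 100,
              V0 = diag(p), nu0 = p + 1)
}

#' @rdname default_prior
#' @param beta0 q x p prior mean of the regression coefficients.
#' @param lambda0 q x q positive-definite row-precision of beta.
#' @param V0 p x p positive-definite inverse-Wishart scale.
#' @param nu0 inverse-Wishart degrees of freedom, `> p - 1`.
#' @export
prior_hyper <- function(beta0, lambda0, V0, nu0) {
  beta0 <- as.matrix(beta0); lambda0 <- as.matrix(lambda0); V0 <- as.matrix(V0)
  q <- nrow(beta0); p <- ncol(beta0)
  if (!identical(dim(lambda0), c(q, q))) stop("lambda0 must be q x q")
  if (!identical(dim(V0), c(p, p))) stop("V0 must be p x p")
  if (nu0 <= p - 1) stop("nu0 must exceed p - 1")
  for (m in list(lambda0, V0))
    if (!isTRUE(all.equal(m, t(m))) ||
        inherits(tryCatch(chol(m), error = identity), "error"))
      stop("lambda0 and V0 must be symmetric positive definite")
  structure(list(beta0 = beta0, lambda0 = lambda0, V0 = V0, nu0 = nu0,
                 p = p, q = q),
            class = "ergmpop_prior")
}

#' Conjugate conditional posterior of (beta, Sigma_eps) given theta
#'
#' Given the n x p matrix of network-level parameters, the matrix-normal /
#' inverse-Wishart prior updates in closed form:
#' `nu_n = nu0 + n`, `Lambda_n = X'X + Lambda0`,
#' `beta_n = Lambda_n^-1 (X'theta + Lambda0 beta0)`,
#' `V_n = V0 + (theta - X beta_n)'(theta - X beta_n) +
#'        (beta_n - beta0)' Lambda0 (beta_n - beta0)`.
#' With n = 0 the posterior equals the prior.
#'
#' @param theta n x p matrix (may have zero rows).
#' @param X n x q design matrix.
#' @param prior an `ergmpop_prior`.
#' @return list of class `ergmpop_posterior` with `beta_n`, `lambda_n`,
#'   `V_n`, `nu_n`.
#' @export
conjugate_posterior <- function(theta, X, prior) {
  theta <- as.matrix(theta); X <- as.matrix(X)
  if (nrow(theta) != nrow(X)) stop("theta and X must have matching rows")
  if (ncol(theta) != prior$p || (nrow(X) > 0 && ncol(X) != prior$q))
    stop("dimension mismatch with prior")
  n <- nrow(X)
  lambda_n <- (if (n > 0) crossprod(X) else matrix(0, prior$q, prior$q)) +
    prior$lambda0
  ch <- tryCatch(chol(lambda_n), error = function(e)
    stop("Lambda_n is singular; supply a proper lambda0 or a full-rank X"))
  beta_n <- chol2inv(ch) %*%
    ((if (n > 0) crossprod(X, theta) else matrix(0, prior$q, prior$p)) +
       prior$lambda0 %*% prior$beta0)
  resid <- theta - (if (n > 0) X %*% beta_n else theta[0, , drop = FALSE])
  db <- beta_n - prior$beta0
  V_n <- prior$V0 + crossprod(resid) + t(db) %*% prior$lambda0 %*% db
  V_n <- (V_n + t(V_n)) / 2
  structure(list(beta_n = beta_n, lambda_n = lambda_n, V_n = V_n,
                 nu_n = prior$nu0 + n, p = prior$p, q = prior$q),
            class = "ergmpop_posterior")
}

#' Draw beta from its conditional matrix-normal posterior
#'
#' `beta | Sigma_eps, theta, X ~ MN(beta_n, Lambda_n^-1, Sigma_eps)`:
#' the draw is `beta_n + A Z B` with `A A' = Lambda_n^-1`, `B'B = Sigma_eps`
#' and `Z` a q x p matrix of standard normals, so `vec(beta)` has covariance
#' `Sigma_eps (x) Lambda_n^-1` (Kronecker).
#'
#' @param post an `ergmpop_posterior`.
#' @param sigma_eps p x p positive-definite residual covariance.
#' @return q x p matrix.
#' @export
sample_beta <- function(post, sigma_eps) {
  U <- chol2inv(chol(post$lambda_n))            # row covariance
  A <- t(chol(U))
  B <- chol(as.matrix(sigma_eps))
  Z <- matrix(rnorm(post$q * post$p), post$q, post$p)
  post$beta_n + A %*% Z %*% B
}

#' Draw Sigma_eps from its conditional inverse-Wishart posterior
#'
#' `Sigma_eps | theta, X ~ InvWishart(V_n, nu_n)`, drawn by inverting a
#' `Wishart(V_n^-1, nu_n)` variate.
#'
#' @param post an `ergmpop_posterior` (or any list with `V_n`, `nu_n`).
#' @return p x p symmetric positive-definite matrix.
#' @export
sample_sigma <- function(post) {
  p <- nrow(post$V_n)
  if (post$nu_n <= p - 1) stop("degrees of freedom must exceed p - 1")
  W <- rWishart(1, df = post$nu_n, Sigma = chol2inv(chol(post$V_n)))[, , 1]
  S <- chol2inv(chol(W))
  (S + t(S)) / 2
}

#' Sampler configuration
#'
#' Defaults mirror the reference analysis: 12,000 iterations with the first
#' 2,000 discarded as burn-in, proposal adaptation every 20 iterations over
#' the first 1,000, and 1,000 auxiliary toggle iterations per exchange
#' update.
#'
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded (must be `< n_iter`).
#' @param parameterization `"cp"` (centred), `"ncp"` (non-centred) or
#'   `"asis"` (interweaved; default).
#' @param aux an [aux_config()] for auxiliary network simulation.
#' @param rng_seed optional integer seed.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param adapt_every,adapt_until proposal adaptation batch length and
#'   window end.
#' @export
sampler_config <- function(n_iter = 12000, burn_in = 2000,
                           parameterization = c("asis", "cp", "ncp"),
                           aux = aux_config(), rng_seed = NULL, thin = 1,
                           adapt_every = 20, adapt_until = 1000) {
  parameterization <- match.arg(parameterization)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (burn_in < 0) stop("burn_in must be non-negative")
  structure(list(n_iter = n_iter, burn_in = burn_in,
                 parameterization = parameterization, aux = aux,
                 rng_seed = rng_seed, thin = as.integer(thin),
                 adapt_every = as.integer(adapt_every),
                 adapt_until = as.integer(adapt_until)),
            class = "ergmpop_config")
}

# internal: fresh sampler state; theta starts at the prior mean mapped
# through the design (a neutral start), Sigma_eps at the identity.
init_state <- function(data, prior) {
  beta <- prior$beta0
  mu <- data$X %*% beta
  list(theta = mu, epsilon = mu * 0, beta = beta, mu = mu,
       sigma_eps = diag(prior$p))
}

# (a) update each theta_i by an exchange move with prior N(x_i' beta,
# Sigma_eps); (b) redraw (beta, Sigma_eps) from the conjugate conditional;
# epsilon is recomputed so theta = mu + epsilon holds identically.
#' Centred-parameterisation Gibbs sweep
#'
#' One sweep of the exchange-within-Gibbs sampler: exchange updates of every
#' network's theta under its conditional Gaussian prior, followed by a joint
#' conjugate draw of (beta, Sigma_eps).
#'
#' @param state sampler state (as produced internally by [run_sampler()]).
#' @param data an [population_data()].
#' @param prior an `ergmpop_prior`.
#' @param props list with `theta` (list of n [proposal_state()]s) and
#'   optionally `beta`.
#' @param cfg an [sampler_config()].
#' @param s_obs optional n x p matrix of precomputed observed statistics.
#' @return list with updated `state`, `props` (unchanged here), logical
#'   `accept_theta` (length n) and `accept_beta` (`NA`, no exchange move on
#'   beta in the centred sweep).
#' @export
gibbs_step_cp <- function(state, data, prior, props, cfg, s_obs = NULL) {
  if (is.null(s_obs)) s_obs <- observed_stats(data)
  n <- data$n
  accept <- logical(n)
  for (i in seq_len(n)) {
    pri <- gaussian_prior(state$mu[i, ], state$sigma_eps)
    up <- exchange_update(state$theta[i, ], data$networks[[i]], data$spec,
                          pri, props$theta[[i]], cfg$aux, s_y = s_obs[i, ])
    state$theta[i, ] <- up$theta
    accept[i] <- up$accepted
  }
  post <- conjugate_posterior(state$theta, data$X, prior)
  state$sigma_eps <- sample_sigma(post)
  state$beta <- sample_beta(post, state$sigma_eps)
  state$mu <- data$X %*% state$beta
  state$epsilon <- state$theta - state$mu
  list(state = state, props = props, accept_theta = accept, accept_beta = NA)
}

# NCP beta exchange move: with epsilon = theta - X beta held fixed, propose
# beta', simulate one auxiliary network per observed network at
# theta_i' = x_i' beta' + eps_i, and accept via the summed exchange ratio
# plus the conditional matrix-normal prior ratio. Sigma_eps is not altered.
ncp_beta_move <- function(state, data, prior, prop_beta, cfg, s_obs) {
  n <- data$n; p <- data$p; q <- data$q
  beta <- state$beta
  beta_prime <- matrix(propose(as.vector(beta), prop_beta), q, p)
  theta_prime <- data$X %*% beta_prime + state$epsilon
  s_aux <- matrix(0, n, p)
  aux <- cfg$aux; aux$init <- "observed"; aux$rng_seed <- NULL
  for (i in seq_len(n)) {
    yp <- simulate_ergm(theta_prime[i, ], data$spec, data$networks[[i]], aux)
    s_aux[i, ] <- attr(yp, "stats")
  }
  lr <- ncp_beta_log_ratio(beta, beta_prime, data$X, s_obs, s_aux,
                           list(beta0 = prior$beta0, lambda0 = prior$lambda0,
                                sigma_eps = state$sigma_eps))
  if (lr >= 0 || log(runif(1)) < lr) {
    state$beta <- beta_prime
    state$mu <- data$X %*% beta_prime
    state$theta <- state$mu + state$epsilon
    list(state = state, accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

# Sigma_eps conditional under the non-centred parameterisation, given both
# epsilon and beta: InvWishart(V0 + eps'eps + (beta-beta0)'Lambda0(beta-beta0),
# nu0 + n + q).
ncp_sigma_draw <- function(state, data, prior) {
  db <- state$beta - prior$beta0
  V <- prior$V0 + crossprod(state$epsilon) + t(db) %*% prior$lambda0 %*% db
  sample_sigma(list(V_n = (V + t(V)) / 2, nu_n = prior$nu0 + data$n + data$q))
}

#' Non-centred-parameterisation Gibbs sweep
#'
#' Exchange updates of each residual epsilon_i (operationally identical to
#' the theta update, by the identity theta = X beta + epsilon), an NCP
#' exchange move on beta (n auxiliary simulations), and a conjugate draw of
#' Sigma_eps given (epsilon, beta).
#'
#' @inheritParams gibbs_step_cp
#' @return as [gibbs_step_cp()], with `accept_beta` the NCP move outcome.
#' @export
gibbs_step_ncp <- function(state, data, prior, props, cfg, s_obs = NULL) {
  if (is.null(s_obs)) s_obs <- observed_stats(data)
  n <- data$n
  accept <- logical(n)
  for (i in seq_len(n)) {
    pri <- gaussian_prior(state$mu[i, ], state$sigma_eps)
    up <- exchange_update(state$theta[i, ], data$networks[[i]], data$spec,
                          pri, props$theta[[i]], cfg$aux, s_y = s_obs[i, ])
    state$theta[i, ] <- up$theta
    accept[i] <- up$accepted
  }
  state$epsilon <- state$theta - state$mu
  mv <- ncp_beta_move(state, data, prior, props$beta, cfg, s_obs)
  state <- mv$state
  state$sigma_eps <- ncp_sigma_draw(state, data, prior)
  list(state = state, props = props, accept_theta = accept,
       accept_beta = mv$accepted)
}

#' ASIS (interweaved) Gibbs sweep
#'
#' Performs the centred sweep, recomputes epsilon = theta - X beta, redraws
#' beta through the non-centred exchange move (Sigma_eps held fixed), and
#' restores theta = X beta + epsilon. Interweaving the two parameterisations
#' improves mixing of the group-level parameters.
#'
#' @inheritParams gibbs_step_cp
#' @return as [gibbs_step_cp()], with `accept_beta` from the NCP sub-step.
#' @export
gibbs_step_asis <- function(state, data, prior, props, cfg, s_obs = NULL) {
  if (is.null(s_obs)) s_obs <- observed_stats(data)
  cp <- gibbs_step_cp(state, data, prior, props, cfg, s_obs)
  state <- cp$state
  state$epsilon <- state$theta - state$mu
  mv <- ncp_beta_move(state, data, prior, props$beta, cfg, s_obs)
  list(state = mv$state, props = props, accept_theta = cp$accept_theta,
       accept_beta = mv$accepted)
}

observed_stats <- function(data) {
  s <- vapply(data$networks, function(g) summary_stats(g, data$spec),
              numeric(data$p))
  # vapply collapses to a vector when p = 1; force an n x p matrix
  t(matrix(s, nrow = data$p))
}

#' Run the exchange-within-Gibbs sampler
#'
#' Fits the multilevel ERGM to a population of networks. Each iteration
#' updates every network's parameter vector by an exchange move (one
#' auxiliary ERGM simulation each), then the group-level (beta, Sigma_eps);
#' with `parameterization = "asis"` an additional non-centred beta exchange
#' move (n auxiliary simulations) is interweaved. Proposals adapt towards a
#' 0.234 acceptance rate during the adaptation window and are frozen
#' afterwards.
#'
#' @param data an [population_data()].
#' @param prior an `ergmpop_prior`; `NULL` for [default_prior()].
#' @param cfg an [sampler_config()].
#' @param verbose print a progress line at each adaptation batch?
#' @return object of class `ergmpop_fit`: arrays `beta` (draws x q x p),
#'   `sigma_eps` (draws x p x p), `theta` (draws x n x p), post-adaptation
#'   acceptance rates, delta traces, and the configuration.
#' @export
run_sampler <- function(data, prior = NULL, cfg = sampler_config(),
                        verbose = FALSE) {
  stopifnot(inherits(data, "ergmpop_population"))
  if (is.null(prior)) prior <- default_prior(data$p, data$q)
  if (prior$p != data$p || prior$q != data$q)
    stop("prior dimensions do not match the data")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)

  n <- data$n; p <- data$p; q <- data$q
  step_fun <- switch(cfg$parameterization, cp = gibbs_step_cp,
                     ncp = gibbs_step_ncp, asis = gibbs_step_asis)
  use_beta_prop <- cfg$parameterization %in% c("ncp", "asis")

  state <- init_state(data, prior)
  s_obs <- observed_stats(data)
  props <- list(
    theta = lapply(seq_len(n), function(i)
      proposal_state(p, adapt_every = cfg$adapt_every,
                     adapt_until = cfg$adapt_until)),
    beta = proposal_state(q * p, adapt_every = cfg$adapt_every,
                          adapt_until = cfg$adapt_until)
  )

  keep_idx <- seq(cfg$burn_in + cfg$thin, cfg$n_iter, by = cfg$thin)
  K <- length(keep_idx)
  out_beta <- array(NA_real_, c(K, q, p))
  out_sigma <- array(NA_real_, c(K, p, p))
  out_theta <- array(NA_real_, c(K, n, p))

  adapt_len <- min(cfg$adapt_until, cfg$n_iter)
  th_hist <- array(NA_real_, c(adapt_len, n, p))
  beta_hist <- matrix(NA_real_, adapt_len, q * p)
  batch_acc_theta <- integer(n); batch_acc_beta <- 0L
  post_acc_theta <- numeric(n); post_acc_beta <- 0; post_n <- 0L
  delta_trace <- list(theta = NULL, beta = NULL)
  kslot <- 0L

  for (iter in seq_len(cfg$n_iter)) {
    sw <- step_fun(state, data, prior, props, cfg, s_obs)
    state <- sw$state
    batch_acc_theta <- batch_acc_theta + sw$accept_theta
    if (use_beta_prop && !is.na(sw$accept_beta))
      batch_acc_beta <- batch_acc_beta + sw$accept_beta

    if (iter <= adapt_len) {
      th_hist[iter, , ] <- state$theta
      beta_hist[iter, ] <- as.vector(state$beta)
      if (iter %% cfg$adapt_every == 0) {
        for (i in seq_len(n)) {
          props$theta[[i]] <- adapt_step(
            props$theta[[i]],
            matrix(th_hist[seq_len(iter), i, ], ncol = p),
            batch_acc_theta[i] / cfg$adapt_every)
        }
        if (use_beta_prop)
          props$beta <- adapt_step(props$beta,
                                   beta_hist[seq_len(iter), , drop = FALSE],
                                   batch_acc_beta / cfg$adapt_every)
        delta_trace$theta <- rbind(delta_trace$theta,
                                   vapply(props$theta, `[[`, 1, "delta"))
        delta_trace$beta <- c(delta_trace$beta, props$beta$delta)
        if (verbose)
          message(sprintf("iter %d: mean theta-accept %.2f, beta-accept %.2f",
                          iter, mean(batch_acc_theta) / cfg$adapt_every,
                          batch_acc_beta / cfg$adapt_every))
        batch_acc_theta[] <- 0L; batch_acc_beta <- 0L
      }
      if (iter == adapt_len) {
        props$theta <- lapply(props$theta, freeze_proposal)
        props$beta <- freeze_proposal(props$beta)
      }
    } else {
      post_acc_theta <- post_acc_theta + sw$accept_theta
      if (use_beta_prop && !is.na(sw$accept_beta))
        post_acc_beta <- post_acc_beta + sw$accept_beta
      post_n <- post_n + 1L
    }

    if (iter > cfg$burn_in && (iter - cfg$burn_in) %% cfg$thin == 0) {
      kslot <- kslot + 1L
      out_beta[kslot, , ] <- state$beta
      out_sigma[kslot, , ] <- state$sigma_eps
      out_theta[kslot, , ] <- state$theta
    }
  }

  structure(
    list(beta = out_beta, sigma_eps = out_sigma, theta = out_theta,
         accept_theta = if (post_n) post_acc_theta / post_n else rep(NA, n),
         accept_beta = if (use_beta_prop && post_n) post_acc_beta / post_n
                       else NA,
         delta_trace = delta_trace, cfg = cfg, prior = prior,
         spec = data$spec, X = data$X, n = n, p = p, q = q,
         n_kept = kslot),
    class = "ergmpop_fit"
  )
}

#' @export
print.ergmpop_fit <- function(x, ...) {
  cat(sprintf(
    "ergmpop fit: %d kept draws (%s), n = %d networks, p = %d stats, q = %d covariates\n",
    x$n_kept, x$cfg$parameterization, x$n, x$p, x$q))
  cat("posterior mean of beta:\n")
  print(beta_posterior_mean(x))
  invisible(x)
}

#' Posterior summaries of the regression coefficients
#'
#' @param fit an `ergmpop_fit`.
#' @return `beta_posterior_mean()`: q x p matrix of posterior means (rows:
#'   covariates, columns: statistics).
#' @export
beta_posterior_mean <- function(fit) {
  m <- apply(fit$beta, c(2, 3), mean)
  dimnames(m) <- list(paste0("x", seq_len(fit$q)), fit$spec$terms)
  m
}

#' @rdname beta_posterior_mean
#' @param row,col coefficient position (covariate row, statistic column).
#' @param level credible level (default 0.95).
#' @return `beta_credible_interval()`: length-2 vector of equal-tailed
#'   quantiles.
#' @export
beta_credible_interval <- function(fit, row = 1, col = 1, level = 0.95) {
  a <- (1 - level) / 2
  quantile(fit$beta[, row, col], c(a, 1 - a), names = FALSE)
}
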
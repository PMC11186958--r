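test_that("default prior has the documented weakly-informative form", {
  pr <- default_prior(3, 1)
  expect_equal(pr$beta0, matrix(0, 1, 3))
  expect_equal(pr$lambda0, matrix(0.01))
  expect_equal(pr$V0, diag(3))
  expect_equal(pr$nu0, 4)
  pr11 <- default_prior(1, 1)
  expect_equal(unlist(pr11[c("beta0", "lambda0", "V0", "nu0")],
                      use.names = FALSE), c(0, 0.01, 1, 2))
  expect_error(prior_hyper(matrix(0, 1, 2), matrix(1), diag(2), 0.5),
               "nu0")
  expect_error(prior_hyper(matrix(0, 2, 1), diag(2), matrix(-1), 3),
               "positive definite")

  # marginal prior variance of beta entries is 100 * (Sigma_eps)_jj
  set.seed(301)
  sig <- matrix(c(0.5, 0.2, 0.2, 0.4), 2, 2)
  post0 <- conjugate_posterior(matrix(0, 0, 2), matrix(0, 0, 1),
                               default_prior(2, 1))
  draws <- t(replicate(4000, drop(sample_beta(post0, sig))))
  expect_equal(apply(draws, 2, var), 100 * diag(sig), tolerance = 0.1)
})

test_that("conjugate posterior matches the closed-form update", {
  pr <- default_prior(2, 2)
  # n = 0: posterior equals prior
  p0 <- conjugate_posterior(matrix(0, 0, 2), matrix(0, 0, 2), pr)
  expect_equal(p0$beta_n, pr$beta0)
  expect_equal(p0$lambda_n, pr$lambda0)
  expect_equal(p0$V_n, pr$V0)
  expect_equal(p0$nu_n, pr$nu0)

  # hand-computed scalar example: exact rational agreement
  ph <- conjugate_posterior(matrix(c(1, 3), 2, 1), matrix(1, 2, 1),
                            prior_hyper(matrix(0), matrix(1), matrix(1), 3))
  expect_equal(ph$lambda_n, matrix(3))
  expect_equal(ph$beta_n, matrix(4 / 3))
  expect_equal(ph$nu_n, 5)
  expect_equal(ph$V_n, matrix(17 / 3))

  # Lambda_n - Lambda0 = X'X exactly; vanishing Lambda0 gives OLS
  set.seed(302)
  X <- cbind(1, rnorm(20)); th <- matrix(rnorm(40), 20, 2)
  pr2 <- default_prior(2, 2)
  pp <- conjugate_posterior(th, X, pr2)
  expect_equal(pp$lambda_n - pr2$lambda0, crossprod(X))
  tiny <- prior_hyper(matrix(0, 2, 2), diag(2) * 1e-10, diag(2), 3)
  expect_equal(conjugate_posterior(th, X, tiny)$beta_n,
               qr.solve(X, th), tolerance = 1e-6)
})

test_that("matrix-normal and inverse-Wishart draws have the right moments", {
  set.seed(303)
  # beta | Sigma: mean beta_n, vec-covariance Sigma_eps (x) Lambda_n^-1
  post <- structure(list(beta_n = matrix(c(1, -1, 0, 2), 2, 2),
                         lambda_n = matrix(c(2, 0.5, 0.5, 1), 2, 2),
                         nu_n = 10, p = 2L, q = 2L),
                    class = "ergmpop_posterior")
  sig <- matrix(c(0.3, -0.1, -0.1, 0.6), 2, 2)
  draws <- t(replicate(8000, as.vector(sample_beta(post, sig))))
  expect_equal(colMeans(draws), as.vector(post$beta_n), tolerance = 0.05)
  expect_equal(cov(draws), kronecker(sig, solve(post$lambda_n)),
               tolerance = 0.12)

  # p = 1: inverse-gamma with shape nu_n/2, scale V_n/2
  post1 <- list(V_n = matrix(3), nu_n = 8)
  s1 <- replicate(8000, drop(sample_sigma(post1)))
  expect_equal(mean(s1), 3 / (8 - 2), tolerance = 0.02)       # V/(nu-p-1)
  expect_equal(mean(1 / s1), 8 / 3, tolerance = 0.05)          # E W = nu V^-1

  # p = 2: empirical mean V_n/(nu_n - p - 1); inverses match Wishart moments
  post2 <- list(V_n = matrix(c(2, 0.4, 0.4, 1), 2, 2), nu_n = 9)
  s2 <- replicate(6000, sample_sigma(post2))
  expect_equal(apply(s2, c(1, 2), mean), post2$V_n / (9 - 2 - 1),
               tolerance = 0.05)
  winv <- apply(s2, 3, function(m) solve(m))
  expect_equal(matrix(rowMeans(winv), 2, 2), 9 * solve(post2$V_n),
               tolerance = 0.2)
  expect_error(sample_sigma(list(V_n = diag(2), nu_n = 0.5)), "degrees")
})

test_that("Gibbs sweeps preserve the theta = X beta + epsilon identity", {
  set.seed(304)
  tm <- network_graph(matrix(0L, 5, 5))
  es <- ergm_spec("edges")
  nets <- lapply(c(-0.5, 0, 0.5), function(t)
    simulate_ergm(t, es, tm, aux_config(300, init = "empty")))
  data <- population_data(nets, matrix(1, 3, 1), es)
  prior <- default_prior(1, 1)
  cfg <- sampler_config(n_iter = 10, burn_in = 1, aux = aux_config(100))
  props <- list(theta = replicate(3, proposal_state(1), simplify = FALSE),
                beta = proposal_state(1))
  state <- ergmpop:::init_state(data, prior)
  for (stepper in list(gibbs_step_cp, gibbs_step_ncp, gibbs_step_asis)) {
    for (k in 1:5) {
      out <- stepper(state, data, prior, props, cfg)
      state <- out$state
      expect_equal(state$theta, state$mu + state$epsilon)
      expect_equal(state$mu, data$X %*% state$beta)
      expect_true(all(eigen(state$sigma_eps)$values > 0))
    }
  }
})

test_that("run_sampler honours its configuration contracts", {
  set.seed(305)
  tm <- network_graph(matrix(0L, 5, 5))
  es <- ergm_spec("edges")
  nets <- lapply(1:2, function(i)
    simulate_ergm(-0.3, es, tm, aux_config(200, init = "empty")))
  data <- population_data(nets, matrix(1, 2, 1), es)
  cfg1 <- sampler_config(n_iter = 6, burn_in = 5, aux = aux_config(50),
                         adapt_until = 4, rng_seed = 42)
  fit1 <- run_sampler(data, cfg = cfg1)
  expect_equal(fit1$n_kept, 1L)
  expect_equal(dim(fit1$beta), c(1, 1, 1))

  cfg2 <- sampler_config(n_iter = 40, burn_in = 10, aux = aux_config(50),
                         adapt_until = 20, rng_seed = 7)
  fit_a <- run_sampler(data, cfg = cfg2)
  fit_b <- run_sampler(data, cfg = cfg2)
  expect_identical(fit_a$beta, fit_b$beta)
  expect_identical(fit_a$theta, fit_b$theta)

  expect_error(sampler_config(n_iter = 10, burn_in = 10), "burn_in")
  expect_error(run_sampler(data, prior = default_prior(2, 1)), "dimensions")
})

test_that("the coupled prior-data chain leaves prior moments invariant", {
  # Geweke-style successive-conditional check on an edges-only model:
  # forward draws y | theta are exact (independent Bernoulli dyads), and the
  # transition is one full centred Gibbs sweep. If the exchange update or a
  # conjugate draw were biased, the beta margin would drift off its prior:
  # mean 0, Var(beta) = E[Sigma]/Lambda0 = V0/(nu0 - 2) = 1 here.
  set.seed(306)
  es <- ergm_spec("edges")
  tm <- network_graph(matrix(0L, 4, 4))
  n <- 2
  prior <- prior_hyper(matrix(0), matrix(1), matrix(4), 6)
  X <- matrix(1, n, 1)
  cfg <- sampler_config(n_iter = 2, burn_in = 1, aux = aux_config(150))
  # wide fixed proposals (sd = 0.1 * sqrt(delta) = 1): the coupled chain must
  # traverse the full prior range of theta, not a posterior-sized
  # neighbourhood, or the variance check is starved by autocorrelation
  props <- list(theta = replicate(n, proposal_state(1, gamma = 1, delta = 100),
                                  simplify = FALSE))
  forward <- function(theta) {
    p_edge <- plogis(theta)
    lapply(seq_len(n), function(i) {
      m <- matrix(0L, 4, 4); ut <- which(upper.tri(m))
      m[ut] <- rbinom(length(ut), 1, p_edge[i])
      network_graph(m + t(m))
    })
  }
  M <- 3000
  betas <- sigmas <- numeric(M)
  sigma <- drop(sample_sigma(list(V_n = prior$V0, nu_n = prior$nu0)))
  beta <- rnorm(1, 0, sqrt(sigma / drop(prior$lambda0)))
  theta <- rnorm(n, beta, sqrt(sigma))
  state <- list(theta = matrix(theta), epsilon = matrix(theta - beta),
                beta = matrix(beta), mu = matrix(rep(beta, n)),
                sigma_eps = matrix(sigma))
  for (m in seq_len(M)) {
    nets <- forward(drop(state$theta))
    data <- population_data(nets, X, es)
    state <- gibbs_step_cp(state, data, prior, props, cfg)$state
    betas[m] <- state$beta
    sigmas[m] <- state$sigma_eps
  }
  expect_lt(abs(mean(betas)), 5 * mcse(betas))
  expect_equal(var(betas), 4 / (6 - 2), tolerance = 0.35)
  expect_equal(mean(sigmas), 4 / (6 - 2), tolerance = 0.25)
})

test_that("CP, NCP and ASIS agree on an enumerable tiny model", {
  set.seed(307)
  es <- ergm_spec("edges")
  tm <- network_graph(matrix(0L, 5, 5))
  nets <- lapply(c(-0.6, -0.2, 0.3), function(t)
    simulate_ergm(t, es, tm, aux_config(400, init = "empty")))
  data <- population_data(nets, matrix(1, 3, 1), es)
  means <- ses <- numeric(3)
  params <- c("cp", "ncp", "asis")
  for (k in seq_along(params)) {
    cfg <- sampler_config(n_iter = 2600, burn_in = 600,
                          parameterization = params[k],
                          aux = aux_config(300), adapt_until = 500,
                          rng_seed = 1000 + k)
    fit <- run_sampler(data, cfg = cfg)
    means[k] <- mean(fit$beta[, 1, 1])
    ses[k] <- mcse(fit$beta[, 1, 1])
  }
  for (a in 1:2) for (b in (a + 1):3)
    expect_lt(abs(means[a] - means[b]), 3 * sqrt(ses[a]^2 + ses[b]^2) + 0.02)
})
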
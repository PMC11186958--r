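#' Adaptive random-walk proposal state
#'
#' Random-walk proposals are a two-component Gaussian mixture centred at the
#' current value:
#' `(1-gamma) N(., 2.38^2 delta Sigma_k / d) + gamma N(., 0.1^2 delta I / d)`,
#' where `Sigma_k` is the sample covariance of all draws kept so far and
#' `delta` a scalar tuned towards a 0.234 acceptance rate. Until `2d` draws
#' are available (or when `Sigma_k` is not positive definite) only the
#' isotropic fallback component is used. Adaptation runs every
#' `adapt_every` iterations within the first `adapt_until` iterations and is
#' frozen afterwards (diminishing adaptation).
#'
#' @param d proposal dimension.
#' @param gamma fallback-component mixture weight (default 0.05).
#' @param delta initial scale factor (default 1).
#' @param adapt_every batch length between adaptations (default 20).
#' @param adapt_until last iteration of the adaptation window (default 1000).
#' @param target targeted acceptance rate (default 0.234).
#' @return list of class `ergmpop_proposal`.
#' @export
proposal_state <- function(d, gamma = 0.05, delta = 1, adapt_every = 20,
                           adapt_until = 1000, target = 0.234) {
  stopifnot(d >= 1, gamma > 0, gamma <= 1, delta > 0)
  structure(
    list(d = as.integer(d), gamma = gamma, delta = delta, Sigma = NULL,
         chol_main = NULL, k = 0L, adapt_every = as.integer(adapt_every),
         adapt_until = as.integer(adapt_until), target = target,
         active = TRUE),
    class = "ergmpop_proposal"
  )
}

#' Draw from the adaptive mixture proposal
#'
#' Symmetric in (current, proposal): both components are Gaussians centred at
#' the current value.
#'
#' @param current numeric d-vector.
#' @param prop an [proposal_state()].
#' @return numeric d-vector.
#' @export
propose <- function(current, prop) {
  d <- prop$d
  if (length(current) != d) stop("dimension mismatch")
  use_main <- !is.null(prop$chol_main) && runif(1) >= prop$gamma
  if (use_main) {
    current + sqrt(prop$delta) * drop(rnorm(d) %*% prop$chol_main)
  } else {
    current + rnorm(d, sd = 0.1 * sqrt(prop$delta / d))
  }
}

#' One adaptation step
#'
#' Call on batch boundaries during the adaptation window: refreshes `Sigma_k`
#' from the full draw history and nudges `log(delta)` by
#' `min(0.5, 1/sqrt(k))` towards the target rate (`k` the batch index) —
#' up when the batch acceptance rate exceeded the target, down otherwise.
#' A no-op once the state is frozen.
#'
#' @param prop an [proposal_state()].
#' @param draws matrix of kept draws so far (rows = iterations).
#' @param batch_rate acceptance rate over the last batch.
#' @return updated `ergmpop_proposal`.
#' @export
adapt_step <- function(prop, draws, batch_rate) {
  if (!prop$active) return(prop)
  prop$k <- prop$k + 1L
  step <- min(0.5, 1 / sqrt(prop$k))
  prop$delta <- prop$delta *
    exp(if (batch_rate > prop$target) step else -step)
  if (!is.null(draws) && nrow(draws) >= 2 * prop$d) {
    S <- cov(draws)
    ch <- tryCatch(chol(2.38^2 * S / prop$d), error = function(e) NULL)
    if (!is.null(ch)) {
      prop$Sigma <- S
      prop$chol_main <- ch
    }
  }
  prop
}

#' @rdname adapt_step
#' @details [freeze_proposal()] ends the adaptation window: subsequent
#'   [adapt_step()] calls leave the state untouched, so the proposal kernel
#'   is fixed and the chain's stationary law is exact thereafter.
#' @export
freeze_proposal <- function(prop) { prop$active <- FALSE; prop }
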
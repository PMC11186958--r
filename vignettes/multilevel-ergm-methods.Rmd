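---
title: "Multilevel Bayesian ERGMs for populations of networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel Bayesian ERGMs for populations of networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ergmpop` is built for settings — typified by brain functional-connectivity
studies — where one observes not a single network but a *population* of
binary undirected networks $y^{(1)}, \dots, y^{(n)}$ on a common, labelled
node set, together with network-level covariates (age, group, cognitive
score). Each network is modelled as an exponential random graph:

$$\pi(y \mid \theta) = \frac{\exp\{\theta^\top s(y)\}}{Z(\theta)},$$

where $s(y)$ is a fixed vector of $p$ summary statistics and
$Z(\theta) = \sum_{y'} \exp\{\theta^\top s(y')\}$ sums over all
$2^{N(N-1)/2}$ graphs — intractable beyond toy sizes. The natural-parameter
map is the identity (the model is linear in $\theta$); curved families with
estimated decay are deliberately out of scope.

The statistics available are the edge count, the count of edges whose
endpoints share a hemisphere label, the count of edges joining homotopic
(mirror) node pairs, and the geometrically weighted edgewise shared partner
statistic

$$\mathrm{GWESP}(y) = e^{\tau} \sum_{w \ge 1}
  \left\{1 - (1 - e^{-\tau})^w\right\} EP_w(y),$$

with $EP_w$ the number of edges whose endpoints share exactly $w$
neighbours. The decay $\tau$ (default 0.9, in the units of the statistic's
geometric down-weighting) attenuates the marginal value of additional shared
partners and is held fixed, never estimated: sampling $\tau$ would make the
family curved and break the linear-in-$\theta$ exchange identity the sampler
relies on. The $w$-sum truncates at $w = N-2$, the maximum attainable
shared-partner count.

Heterogeneity across networks is captured by a Gaussian multilevel layer:

$$\theta^{(i)} \sim \mathcal{N}(x_i^\top \beta, \Sigma_\epsilon),$$

with $x_i \in \mathbb{R}^q$ the network-level covariates, $\beta$ a
$q \times p$ coefficient matrix and $\Sigma_\epsilon$ a $p \times p$
residual covariance. The conditionally conjugate prior is matrix-normal /
inverse-Wishart:

$$\beta \mid \Sigma_\epsilon \sim \mathcal{MN}(\beta_0, \Lambda_0^{-1},
\Sigma_\epsilon), \qquad \Sigma_\epsilon \sim \mathcal{W}^{-1}(V_0, \nu_0).$$

**A note on dimensions.** For the conjugacy to be well-defined with $\beta$
being $q \times p$ and $\Sigma_\epsilon$ being $p \times p$, the row scale
$\Lambda_0$ must be $q \times q$ and the inverse-Wishart scale $V_0$ must be
$p \times p$ with $\nu_0 > p - 1$. Published accounts of this model family
sometimes swap $p$ and $q$ in stating these defaults; `default_prior(p, q)`
uses the dimension-consistent reading: $\beta_0 = 0$,
$\Lambda_0^{-1} = 100\, I_q$ (flat coefficients), $V_0 = I_p$,
$\nu_0 = p + 1$ (the smallest integer giving a proper prior). Rows of the
design matrix are the $x_i^\top$ — the only convention under which $X\beta$
is $n \times p$.

## Posterior computation

The posterior over $(\{\theta^{(i)}\}, \beta, \Sigma_\epsilon)$ is *doubly
intractable*: every likelihood evaluation involves $Z(\theta^{(i)})$. The
sampler combines three ingredients.

**Exchange updates.** To update $\theta^{(i)}$, propose $\theta'$ from a
symmetric random walk, simulate an auxiliary network
$y' \sim \pi(\cdot \mid \theta')$, and accept with probability
$\min\{1, \exp((\theta' - \theta)^\top (s(y) - s(y')))\,
\pi(\theta')/\pi(\theta)\}$: the auxiliary draw makes both normalising
constants cancel. Auxiliary networks come from `simulate_ergm()`, a
single-dyad toggle Metropolis–Hastings run of `n_aux` iterations (default
1,000) driven by change statistics computed in C++. The auxiliary chain for
exchange updates starts at the observed network — a variance-reduction
convention this package adopts as its own choice (the literature is
typically silent on initialisation); posterior-predictive simulation instead
starts from an Erdős–Rényi graph of matched density so the predictive draws
do not inherit the observed topology. Auxiliary draws are approximate ERGM
samples; the approximation deteriorates when the fixed `n_aux` is small
relative to the graph, and `simulate_ergm()` warns for $N > 60$.

**Exchange-within-Gibbs and ASIS.** A sweep under the centred
parameterisation (CP) updates every $\theta^{(i)}$ by an exchange move with
conditional prior $\mathcal{N}(x_i^\top\beta, \Sigma_\epsilon)$, then draws
$(\beta, \Sigma_\epsilon)$ jointly from the closed-form conditional. Under
the non-centred parameterisation (NCP) the residuals
$\epsilon^{(i)} = \theta^{(i)} - x_i^\top\beta$ are held and $\beta$ enters
every network's likelihood, so its update is itself an exchange move
requiring $n$ auxiliary simulations. CP mixes well when the $\theta^{(i)}$
are strongly identified by their networks, NCP when they are weak; the
ancillarity–sufficiency interweaving strategy (ASIS, the default) performs
the CP sweep, recomputes $\epsilon$, redraws $\beta$ through the NCP
exchange move with $\Sigma_\epsilon$ held fixed, and restores
$\theta = X\beta + \epsilon$. The identity $\theta = X\beta + \epsilon$
holds exactly after every sub-step and is asserted in the tests.
$\Sigma_\epsilon$ is *not* refreshed inside the NCP sub-step: whether it
should be is not derivable from published algorithm statements, and the
joint-correctness (Geweke-style) test guards the validity of the choice
made. The update order — $\theta$-block, $(\beta, \Sigma_\epsilon)$, then
the NCP $\beta$ move — is fixed.

**Adaptive proposals.** All random-walk proposals are the two-component
mixture
$(1-\gamma)\,\mathcal{N}(\cdot, 2.38^2 \delta_k \Sigma_k / d) +
\gamma\,\mathcal{N}(\cdot, 0.1^2 \delta_k I / d)$ with $\gamma = 0.05$,
$\Sigma_k$ the sample covariance of the full draw history and $\delta_k$ a
scalar steered towards the classical 0.234 acceptance target: every 20
iterations during the first 1,000, $\log \delta$ moves by
$\min(0.5, 1/\sqrt{k})$ — $k$ the *batch* index — up if the batch acceptance
exceeded 0.234, down otherwise. (Some statements of this rule in the
literature have the direction inverted, which would drive acceptance to
zero; this package uses the direction of the underlying adaptive-Metropolis
scheme.) Until $2d$ draws exist, or if $\Sigma_k$ is not positive definite,
only the isotropic fallback component is used. Adaptation freezes after the
window, so the post-window kernel is fixed and the chain's stationary law
exact. Per-network updates are executed serially under one RNG stream;
results are therefore bit-reproducible given the seed.

Defaults mirror the reference analysis: 12,000 iterations, 2,000 burn-in,
adaptation over the first 1,000, `n_aux` = 1,000. Initial values are
neutral: $\theta^{(0)} = X\beta_0$ (the prior mean), $\Sigma_\epsilon = I$.
The first few hundred iterations therefore start far from sparse-network
parameter values; the adaptation window absorbs this transient, and the
default burn-in discards it.

## Goodness of fit

`posterior_predictive()` draws $S$ (default 100) posterior samples of
$\beta$ uniformly at random and simulates, for each draw, one network per
*distinct design row* at the mean parameter $x^\top \beta^{(s)}$. Whether
predictive networks should be simulated per individual or per group is
ambiguous in the figure-level descriptions this mimics; per-distinct-row is
the implemented reading, and an `include_residual` flag optionally adds a
$\Sigma_\epsilon^{(s)}$ residual draw for dispersion-aware checks (off by
default, matching the literal "simulate at the mean" reading).
`gof_summary()` then compares degree, geodesic-distance (BFS shortest
paths, disconnected pairs in a distinct infinity bin) and edgewise
shared-partner distributions of the observed networks against pointwise
quantile bands (default 90%) over the predictive networks.

## Synthetic data

`generate_population()` reproduces three simulation designs on 30-node
graphs split into two 15-node hemispheres (node $j$ mirrored with
$j + N/2$), under the 3-term model (edges, within-hemisphere match, GWESP
$\tau = 0.9$):

* **no covariate**: $\theta_i \sim \mathcal{N}(\mu, \Sigma)$ with
  $\mu = (-3, 0.5, 0.5)^\top$;
* **continuous**: $\mu_i = b + \frac{i-1}{n-1}(a - b)$ with
  $a = (-3, 0.5, 0.5)^\top$, $b = (-2.6, 0.5, 0.2)^\top$, design rows
  $(1, \frac{i-1}{n-1})$ so the true coefficient rows are $(b, a-b)$. (The
  source account pairs the $\mu_i$ formula with covariate $(i-1)/n$; the two
  are inconsistent, and the $\mu_i$ formula is taken as authoritative so
  that means run exactly from $b$ to $a$.);
* **binary**: two groups of $n$ networks with means $a$ and $b$ and a
  one-hot two-column design, so the coefficient rows are $(a, b)$.

In all cases
$\Sigma = \frac{1}{50}\begin{pmatrix}1 & -0.5 & 0\\ -0.5 & 0.5 & 0\\ 0 & 0 & 0.5\end{pmatrix}$.
Networks are simulated with a long toggle run (40 sweeps of the dyads from
a sparse random start, adequate for these sparse, weakly clustered models).
These truths put the model in a mildly near-degenerate regime: the test
suite asserts that generated densities stay well below one half (every
network below 0.45, mean below 0.25) while remaining non-trivial, and
upper-tail GWESP draws can push individual realisations towards the top of
that range. That is a property of the stated model, not a generator
artefact.

The correlation-matrix front end emulates the thresholding route from
functional-connectivity data: `threshold_correlation()` places an edge where
$C_{kl} \ge r$, and `find_threshold()` picks $r$ so the mean node degree
across all networks is the largest value not exceeding a target (default 3,
the usual sparse-connectome operating point). Because mean degree is a step
function of $r$, the selected $r$ satisfies its defining inequality exactly.
`generate_correlation_population()` supplies stand-in matrices from a
shared-loading factor model with subject-level loading noise — synthetic by
construction; it reproduces block-community structure but none of the
temporal or spatial autocorrelation of real fMRI-derived matrices. A green
thresholding test therefore establishes the correctness of the Eq-style
edge rule and the degree targeting, not realism of the input matrices.

## What the tests do and do not establish

Correctness is anchored to independent oracles at small sizes: exhaustive
enumeration of all graphs on $N \le 6$ nodes (`exact_log_partition`,
`exact_pmf`), 1-D quadrature for edges-only posteriors, brute-force
recomputation for change statistics, closed-form moments for the conjugate
draws, and a successive-conditional (Geweke-style) coupling that leaves the
prior invariant only if every update is unbiased. The total-variation check
of the sampler law runs at $N = 4$: with $10^4$ draws the multinomial noise
floor at $N = 5$ (1,024 cells) already exceeds the 0.05 criterion, so
$N = 4$ is the largest size at which the check is informative. Recovery
tests run the full pipeline at reduced scale (3,000 iterations, `n_aux`
750) and check that generative group-level means are covered by 95%
credible intervals and recovered within 0.5 on the log-odds scale —
deliberately coarse bounds that accommodate Monte-Carlo error at this
scale. None of this certifies mixing on large, dense or strongly degenerate
networks, where fixed-length auxiliary runs are known to degrade.

## Numerical choices and degenerate inputs

* Cholesky factorisations back all Gaussian and Wishart draws; a
  non-positive-definite adapted $\Sigma_k$ silently reverts the proposal to
  its fallback component rather than aborting the chain.
* `conjugate_posterior` fails loudly when $\Lambda_n$ is singular (possible
  only with an improper $\Lambda_0$ and rank-deficient $X$);
  `population_data` warns on rank-deficient designs.
* Empty and complete graphs are valid everywhere: GWESP of an edgeless
  graph is 0; the geodesic infinity bin absorbs disconnected pairs; ESP
  counts always sum to the edge count.
* Ties in `threshold_correlation` are kept (`>=`), and `find_threshold`
  always has the empty-graph threshold available, so a degree target of 0
  is reachable.

## Known limitations

* Auxiliary-network bias: exchange acceptance uses finite toggle runs, so
  the targeted posterior is an approximation improving in `n_aux`; no
  perfect sampling is attempted.
* Undirected binary networks only; no dyadic covariates, no curved terms,
  no missing-data handling, no model selection across statistic sets.
* Per-network updates are serial; the algorithm parallelises naturally but
  this implementation favours auditability and exact reproducibility.
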
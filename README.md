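# ergmpop

Bayesian multilevel exponential random graph models (ERGMs) for
**populations of networks** — e.g. per-subject brain functional-connectivity
networks on a shared parcellation — with network-level covariates such as
age, group or cognitive score.

## The model

Each observed binary undirected network $y^{(i)}$ on $N$ labelled nodes is
an ERGM,

$$\pi(y \mid \theta^{(i)}) \propto \exp\{\theta^{(i)\top} s(y)\},$$

with summary statistics $s(y)$ drawn from: edge count, same-hemisphere edge
count, homotopic (mirror-pair) edge count, and the geometrically weighted
edgewise shared partner statistic GWESP with fixed decay $\tau$. Per-network
parameters are tied together by a multivariate Gaussian regression on
network-level covariates $x_i \in \mathbb{R}^q$:

$$\theta^{(i)} \sim \mathcal{N}(x_i^\top \beta, \Sigma_\epsilon), \qquad
\beta \mid \Sigma_\epsilon \sim \mathcal{MN}(\beta_0, \Lambda_0^{-1},
\Sigma_\epsilon), \qquad \Sigma_\epsilon \sim \mathcal{W}^{-1}(V_0, \nu_0).$$

The ERGM normalising constant is intractable, so the posterior is *doubly
intractable*. Inference uses the **exchange algorithm** inside a Gibbs
sweep: each $\theta^{(i)}$ update simulates an auxiliary network at the
proposed parameter (single-dyad toggle Metropolis–Hastings in C++), which
cancels the normalising constants in the acceptance ratio;
$(\beta, \Sigma_\epsilon)$ is conjugate given $\theta$. The default sampler
interweaves centred and non-centred parameterisations (**ASIS**) for better
group-level mixing, with adaptive random-walk proposals targeting a 0.234
acceptance rate. Posterior-predictive goodness-of-fit compares degree,
geodesic-distance and edgewise-shared-partner distributions of the data
against credible bands from networks simulated at posterior draws.

See `vignettes/multilevel-ergm-methods.Rmd` for the full account of the
model, algorithms, defaults and limitations.

## Worked example

Simulate a population of ten 30-node two-hemisphere networks whose
parameters are drawn around $\mu = (-3, 0.5, 0.5)$ — sparse graphs with a
moderate preference for within-hemisphere edges and for triangles — then
refit the model:

```r
library(ergmpop)

des <- simulation_design("no_covariate", n = 10, rng_seed = 101)
pop <- generate_population(des)

cfg <- sampler_config(n_iter = 3000, burn_in = 1000,
                      parameterization = "asis",
                      aux = aux_config(500), rng_seed = 202)
fit <- run_sampler(pop$data, cfg = cfg)

beta_posterior_mean(fit)
#>       edges nodematch.hemisphere     gwesp
#> x1 -3.04263             0.477977 0.5214454
beta_credible_interval(fit, 1, 1)   # 95% CI for the edges mean
#> [1] -3.433225 -2.679575
round(fit$accept_theta, 2)          # post-adaptation acceptance rates
#> [1] 0.19 0.21 0.22 0.35 0.23 0.25 0.27 0.30 0.21 0.28
```

The posterior mean of the group-level **edges** coefficient, −3.04, sits on
the log-odds scale: a unit increase in the edge count multiplies a graph's
probability by $e^{\theta}$, so negative values encode sparsity. The
generative value −3 is inside the 95% credible interval, and all
random-walk acceptance rates sit in the (0.1, 0.5) band around the 0.234
target. Positive `nodematch.hemisphere` (0.48) and `gwesp` (0.52) means
recover the simulated preference for intra-hemisphere connections and
triadic clustering.

Goodness of fit:

```r
preds <- posterior_predictive(fit, pop$data$networks[[1]],
                              gof_config(S = 100, rng_seed = 7))
gs <- gof_summary(pop$data$networks, preds, gof_config(S = 100))
plot(gs)   # degree / geodesic / shared-partner bands vs observed medians
```

The same workflows are scriptable (`inst/cli/ergmpop`):

```sh
Rscript inst/cli/ergmpop simulate --design none --n 10 --seed 1 --out pop/
Rscript inst/cli/ergmpop fit --bundle pop/ --param asis --iters 12000 \
        --burnin 2000 --seed 2 --out fit/
Rscript inst/cli/ergmpop gof --fit fit/ --bundle pop/ --S 100 --out gof/
```

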
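# ecmle — marginal likelihood estimation by ellipsoid-covered HPD regions

`ecmle` estimates the marginal likelihood (model evidence)

$$Z = \int \pi(\theta)\,L(\theta)\,d\theta$$

from posterior draws, for Bayesian model comparison. All estimators in the
package are instances of the Gelfand–Dey (reciprocal importance sampling)
identity: for any density $\varphi$ on the posterior support,

$$\hat Z^{-1} \;=\; \frac{1}{T}\sum_{t=1}^{T}
  \frac{\varphi(\theta^{(t)})}{\pi(\theta^{(t)})\,L(\theta^{(t)})}$$

is unbiased for $Z^{-1}$. The classical harmonic mean estimator
($\varphi = \pi$) has unbounded variance for most models; choosing
$\varphi$ *uniform on a bounded high posterior density (HPD) region* keeps
every importance ratio bounded. The package's main estimator (ECMLE) takes
that region to be a union of disjoint ellipsoids fitted adaptively to the
empirical HPD region of the draws,

$$\hat Z^{-1} = \frac{1}{T\,V(\mathcal E)} \sum_{t}
  \frac{\mathbf 1\{\theta_t\in\mathcal E\}}{\pi(\theta_t)L(\theta_t)},
\qquad
V(\mathcal E) = \sum_j \frac{\pi^{d/2}}{\Gamma(d/2+1)}\sqrt{\det\Sigma_j},$$

so the region adapts to multimodal or strongly curved posteriors (where a
single ellipsoid either misses modes or swallows low-density troughs) while
its volume stays exactly computable. Cross-fitting — building the region on
one half of the draws and averaging on the other — preserves unbiasedness.

Also included, as baselines and diagnostics:

* `harmonic_mean_nr()` — the classical harmonic mean estimator;
* `gelfand_dey()` with `phi_gaussian()` / `phi_truncated_gaussian()` —
  Gaussian and ellipsoid-truncated Gaussian instrumental densities;
* `thames_estimate()` / `tthames_estimate()` — truncated harmonic mean
  estimators on a single moment ellipsoid (radius $\sqrt{d+1}$ by
  default), optionally intersected with the empirical HPD set (volume by
  Monte Carlo);
* `pwk_estimate()` — the partition weighted kernel estimator on
  standardized spherical shells;
* `variance_proxy()` — a Monte Carlo proxy proportional to
  $\mathrm{Var}(\hat Z^{-1})$, for comparing HPD levels and regions;
* three benchmark model families with exact evidence and exact posterior
  samplers — `gaussian_conjugate()`, `mixture_prior()`, `rosenbrock()` —
  used throughout the tests and experiments;
* experiment drivers (`run_replications()`, `alpha_sweep()`) and a CLI.

## Worked example

Evidence of a bivariate Gaussian model with a two-component Gaussian
mixture prior — a benchmark whose exact evidence is available in closed
form:

```r
library(ecmle)

mix <- mixture_prior(n = 20, d = 2, weights = c(0.5, 0.5),
                     means = list(c(-3, -3), c(3, 3)), seed = 1)
mix$model$log_evidence
#> [1] -56.20959

draws <- sample_posterior(mix$target, 20000, seed = 2)
est <- ecmle_evidence(draws, mix$target, alpha = 0.75, k = 0.05, seed = 3)
est
#> Evidence estimate [ecmle]
#>   log Z: -56.20717
#>   draws inside region: 7187 of 10000
#>   log region volume: -0.952933

exp(est$log_z - mix$model$log_evidence)   # Zhat / Z
#> [1] 1.002422
```

The 20,000 exact posterior draws are split in half; the HPD threshold at
level `alpha = 0.75` is taken on the first 10,000; the disjoint ellipsoid
covering is built from a 5% candidate subsample of the HPD points; the
estimator averages over the held-out 10,000 draws, of which 7,187 fall in
the region. The estimate lands within 0.3% of the true evidence. Swapping
the two halves and averaging (`cross_fit = TRUE`) tightens it further and
reports the spread of the two half-estimates as a variability indicator.

## Command line

A thin CLI wraps the same functions (installed under
`system.file("exec", "ecmle", package = "ecmle")`):

```sh
ecmle simulate  --model rosenbrock --d 2 --n 20 --draws 20000 --seed 1 \
                --out draws.csv
ecmle estimate  --method ecmle --alpha 0.75 --model rosenbrock --d 2 \
                --n 20 --seed 1 --draws draws.csv
ecmle replicate --config experiment.yaml --out records.csv
ecmle sweep     --config experiment.yaml --out sweep.csv
```

Draw files are CSV with header `theta_1,...,theta_d,log_post`; estimates
are emitted as JSON; replication and sweep tables as CSV with numbers at
17 significant digits. Seeds and settings are logged to stderr.

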
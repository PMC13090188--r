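---
title: "Evidence estimation with ellipsoid-covered HPD regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence estimation with ellipsoid-covered HPD regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmle)
```

## The problem

The marginal likelihood (evidence)
$$Z = \int \pi(\theta)\,L(\theta)\,d\theta$$
normalizes the posterior and is the quantity Bayes factors are built from.
It is rarely available in closed form. Given draws
$\theta^{(1)},\dots,\theta^{(T)}$ from the posterior, the Gelfand–Dey
identity
$$\mathbb{E}^{\pi(\cdot\mid x)}\!\left[\frac{\varphi(\theta)}
  {\pi(\theta)L(\theta)}\right] = \frac{1}{Z}$$
holds for any probability density $\varphi$ supported on the posterior
support, and justifies the reciprocal importance-sampling estimator
$$\hat Z^{-1} = \frac{1}{T}\sum_{t=1}^{T}
  \frac{\varphi(\theta^{(t)})}{\pi(\theta^{(t)})L(\theta^{(t)})},$$
which is unbiased for $Z^{-1}$. The classical harmonic mean estimator is
the special case $\varphi = \pi$ and is notoriously unstable: its variance
is unbounded whenever $\varphi$ has heavier tails than the posterior. The
cure is a $\varphi$ with *bounded* support inside a high posterior density
(HPD) region, which keeps every importance ratio bounded.

This package implements that family of bounded harmonic-mean estimators.
The main estimator takes $\varphi$ uniform on a union of disjoint
ellipsoids $\mathcal{E} = \bigcup_k \mathfrak{e}(\mu_k, \Sigma_k)$ fitted
adaptively to the empirical HPD region, so that
$$\hat Z^{-1} = \frac{1}{T\,V(\mathcal{E})}\sum_{t}
  \frac{\mathbf{1}\{\theta_t \in \mathcal{E}\}}
       {\pi(\theta_t)L(\theta_t)},$$
with $V(\mathcal{E}) = \sum_j \pi^{d/2}/\Gamma(d/2+1)\sqrt{\det\Sigma_j}$
computable exactly because the members are pairwise disjoint. Unlike a
single moment-matched ellipsoid, the union conforms to multimodal,
curved or skewed posteriors without enclosing low-density troughs.

## The procedure

Three steps, mirroring the package API:

1. **Partition** (`hpd_partition()`): the $2T$ draws are split into a
   construction half and an evaluation half (contiguous blocks by default,
   respecting MCMC time order; a seeded permutation for i.i.d. draws).
   The HPD threshold $\log c$ at level $\alpha$ is the smallest of the
   $\lceil\alpha T\rceil$ largest log unnormalized posterior values of the
   construction half — an order statistic, not an interpolated quantile,
   so there is no interpolation ambiguity; ties at $c$ count as HPD.
   Building the region on one half and averaging on the other keeps
   $\hat Z^{-1}$ unbiased; `cross_fit = TRUE` swaps the roles and averages
   the two estimates on the $\hat Z^{-1}$ scale.

2. **Covering** (`build_covering()`): a seeded random subsample of the
   HPD points at rate $k$ (default 0.05) forms the candidate centers,
   processed in decreasing density order. Each candidate is fitted with a
   locally adapted ellipsoid: the primary axis points at the nearest
   low-density point, the frame is completed by Gram–Schmidt, and each
   semi-axis is the smaller of the two bisection radii at which the
   log-density crosses $\log c$ along the $\pm$ axis directions. A
   tentative ellipsoid is accepted only if its bounding sphere is disjoint
   from every accepted member (the sufficient certificate
   $\|\mu_i-\mu_j\| \ge s_{\max,i}+s_{\max,j}$); after acceptance,
   candidates inside it are pruned.

3. **Evaluation** (`ecmle_estimate()`): the held-out half is scanned for
   membership, and the sum is accumulated in log space.

`ecmle_evidence()` runs the three steps in one call.

## Tunable parameters

* `alpha` — HPD level in $(0,1]$. Levels around 0.75–0.80 are the stable
  region: small $\alpha$ throws away volume (and evaluation draws), large
  $\alpha$ drags the region into the tails where $1/\pi(\theta)L(\theta)$
  blows up. For a bivariate Gaussian posterior the variance proxy below
  has its analytic minimum at coverage $1-e^{-x^\ast}\approx 0.797$, which
  is why the default is 0.75 and the sweep drivers include 0.80.
* `k` — candidate subsampling rate, default 0.05 (typical useful range
  0.05–0.1). Only enough candidates to seed each density blob are needed,
  because accepted ellipsoids prune their interiors.
* `r` (single-ellipsoid estimators) — radius of the moment ellipsoid,
  default $\sqrt{d+1}$, the variance-minimizing choice when the posterior
  is Gaussian.
* `n_vol` — Monte Carlo draws for the intersection volume of the
  HPD-truncated single-ellipsoid estimator (default $10^5$ in
  `tthames_estimate()`). That estimator is biased through the volume
  plug-in; the relative Monte Carlo volume error is reported in its
  diagnostics.

## Numerical choices

* All accumulation is in log space (log-sum-exp). Posterior density
  values at realistic sample sizes underflow double precision otherwise.
* Boundary search: a doubling expansion brackets the threshold crossing,
  then bisection refines it to `tol = 1e-6` on the log-density scale. The
  initial step is the median distance from the candidate to its 10
  nearest HPD neighbours (a local resolution scale); the search radius is
  capped at 10 times the coordinate range of the construction half. When
  a direction never crosses the threshold (ridges, flat tails), the
  semi-axis falls back to the span of the HPD points projected on that
  direction, capped, and the fit is flagged in the diagnostics.
* Degenerate-fit guards: an ellipsoid is discarded when any semi-axis is
  below $10^{-8}$ of the coordinate scale, or when its *largest* semi-axis
  is below the local 10-nearest-neighbour distance scale. The second
  guard matters in practice: candidates sitting just above the threshold
  near the fuzzy empirical HPD boundary otherwise produce tiny boundary
  ellipsoids — artifacts of sampling noise in the boundary position, not
  resolvable density structure — that occasionally pass the disjointness
  certificate and clutter the covering. The guard compares the largest
  axis, not the smallest, so that thin ridge-following ellipsoids (the
  Rosenbrock banana) survive. With it, a three-mode Gaussian-mixture
  posterior is covered by exactly three ellipsoids across seeds and
  sample sizes; without it, a handful of boundary slivers typically tag
  along.
* Ellipsoid membership is inclusive ($\le 1$, with a $10^{-9}$ relative
  slack for round-off); disjointness uses the bounding-sphere certificate
  only, which is what the construction promises — no sharper
  ellipsoid-intersection test is attempted.
* The mixture-prior benchmark combines component evidences with the
  *prior* weights, $Z = \sum_k \omega_k Z_k$: this is the self-consistent
  form (direct integration of the prior mixture against the likelihood)
  and is the one validated by the quadrature oracle in the test suite.

## The variance proxy

For a uniform-on-region instrumental density, the second moment of
$\hat Z^{-1}$ reduces to
$$\mathbb{E}\left[\hat Z^{-2}\right] = \frac{1}{T\,V(\mathcal{R})^2}
  \int_{\mathcal{R}} \frac{1}{\pi(\theta)L(\theta)}\,d\theta,$$
estimated by uniform Monte Carlo sampling on $\mathcal{R}$
(`variance_proxy()`). It is proportional to the estimator variance and is
used for *relative* comparisons only — across HPD levels or across
instrumental regions; its absolute scale carries no meaning, which is why
the sweep drivers report it alongside, never instead of, replication
variances.

## Benchmark models and what the generator does (and does not) emulate

Three closed-form families double as the synthetic-data generators for
every test:

* `gaussian_conjugate()` — $X_i \sim N_d(\mu, I)$, prior
  $\mu \sim N_d(0, sI)$; posterior $N_d(\hat m, \hat s I)$ with
  $\hat m = n\bar x/(n+1/s)$, $\hat s = 1/(n+1/s)$, and a closed-form
  $\log Z$ locked in by a quadrature oracle before any estimator test
  depends on it. Defaults $n=20$, $s=1$, $d=2$, $\mu=(1,1)$.
* `mixture_prior()` — $X_i \sim N_d(\mu, \Sigma_X)$ with a $K$-component
  Gaussian mixture prior; the posterior is again a $K$-component mixture
  with known weights, means and covariances, so exact posterior sampling
  is available. Defaults: $K=2$, $\omega=1/2$, $\xi = (\mp 3,\mp 3)$,
  $S_k = \Sigma_X = I$, $n=20$. Note that under the generative draw
  (prior component, then $\mu$, then data) the posterior weights
  typically collapse onto the component that generated the data; a
  *balanced* multimodal posterior requires a dataset centered between the
  prior modes, which the test suite constructs explicitly (observations
  centered at the origin, tight prior components on a circle).
* `rosenbrock()` — sufficient-statistic form of the banana-shaped
  benchmark: $\bar Y_j \mid \theta \sim N(\mu_j(\theta), \sigma^2/n)$
  with $\mu_1 = \theta_1$,
  $\mu_j = \theta_j + b_{j-1}(\theta_{j-1}^2 - a_{j-1})$, flat prior.
  Because $\eta = \mu(\theta)$ is triangular with unit Jacobian, $Z = 1$
  exactly for every configuration, and exact draws come from inverting
  the map on independent Gaussians. The shape constants are not pinned
  down by the closed form; the defaults $a_j = 1$, $b_j = 10$,
  $\sigma = 1$ give the classic strongly curved banana while keeping
  desk-scale runs stable.

All three admit *exact* posterior sampling, so what passing tests show is
the behavior of the estimators given genuinely posterior-distributed
draws. Real MCMC output adds autocorrelation and possible
non-convergence, which none of the generators emulate; the contiguous
block-split is the only concession to MCMC structure. External draws
enter through `read_draws_csv()` with the log-posterior column validated
against the model when one is supplied.

## Problem sizes used in the shipped experiments

The replication studies shipped with the package run at desk scale:
50 replications of $2T = 20{,}000$ exact draws for the evidence-ratio
checks, 30 replications per level for the stability sweep, 10 proxy
evaluations of $20{,}000$ uniform draws per HPD level, and 200
replications of $2T = 2{,}000$ draws for the unbiasedness batteries.
These sizes make the Monte Carlo standard errors small enough for
3-standard-error assertions while keeping a full run in minutes on one
core; the experiment drivers accept larger budgets through
`experiment_config()` when sharper comparisons are wanted.

## Known limitations

* The bounding-sphere certificate is conservative: genuinely disjoint but
  snugly interleaved ellipsoids can be rejected, slightly under-covering
  tight multimodal structure. Only the certificate is promised.
* The covering is not guaranteed to sit inside the exact HPD region;
  unbiasedness only needs positive posterior density on the region, so
  inclusion affects variance, not validity.
* The HPD-truncated single-ellipsoid estimator is biased through its
  Monte Carlo volume; treat its diagnostics (`vol_rel_se`,
  `fallback_level`) as part of the answer.
* In high dimension the ellipsoid union inherits the usual curse: a
  fixed-size sample resolves the HPD boundary less well, and coverings
  become many small ellipsoids with shrinking held-out coverage. The
  dimension sweep driver exists precisely to watch that degradation.
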
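#' Evidence estimate objects
#'
#' All estimators return this container. The estimators are unbiased for
#' \eqn{Z^{-1}}, so the natural scale of the estimate is
#' `log_inv_z = -log_z`; both are stored, with all accumulation done in log
#' space (log-sum-exp) to avoid underflow of the posterior density values.
#'
#' @param method method tag.
#' @param log_z the log evidence estimate \eqn{\log \hat Z}.
#' @param log_region_volume log volume of the instrumental region (if any).
#' @param n_inside number of evaluation draws inside the region.
#' @param n_eval size of the evaluation sample `T`.
#' @param settings list of settings (alpha, k, r, seeds, ...).
#' @param diagnostics list of method diagnostics.
#' @return object of class `evidence_estimate`.
#' @export
evidence_estimate <- function(method, log_z, log_region_volume = NA_real_,
                              n_inside = NA_integer_, n_eval = NA_integer_,
                              settings = list(), diagnostics = list()) {
  structure(
    list(method = method, log_z = log_z, log_inv_z = -log_z,
         inv_z = exp(-log_z), log_region_volume = log_region_volume,
         n_inside = n_inside, n_eval = n_eval, settings = settings,
         diagnostics = diagnostics),
    class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat("Evidence estimate [", x$method, "]\n", sep = "")
  cat("  log Z:", format(x$log_z), "\n")
  if (!is.na(x$n_inside))
    cat("  draws inside region:", x$n_inside, "of", x$n_eval, "\n")
  if (!is.na(x$log_region_volume))
    cat("  log region volume:", format(x$log_region_volume), "\n")
  invisible(x)
}

#' Evidence estimate from an ellipsoid covering (core estimator)
#'
#' With the instrumental density uniform on the disjoint ellipsoid union
#' \eqn{\mathcal E}, the Gelfand-Dey estimator becomes
#' \deqn{\hat Z^{-1} = \frac{1}{T\,V(\mathcal E)} \sum_{t}
#'   \frac{\mathbf 1\{\theta_t \in \mathcal E\}}{\pi(\theta_t)L(\theta_t)},}
#' summed over the evaluation half only (cross-fitting keeps it unbiased).
#'
#' @param covering an `hpd_covering` (from [build_covering()]) or a bare
#'   [ellipsoid_union()].
#' @param eval_half `posterior_draws` for the evaluation half; must be
#'   disjoint from the construction half.
#' @param settings settings carried into the estimate record.
#' @return an [evidence_estimate()]; errors when no evaluation draw falls
#'   inside the region.
#' @export
ecmle_estimate <- function(covering, eval_half, settings = list()) {
  union <- if (inherits(covering, "hpd_covering")) covering$union else covering
  stopifnot(inherits(union, "ellipsoid_union"))
  inside <- ellipsoid_contains(union, eval_half$theta)
  n_inside <- sum(inside)
  n_eval <- length(eval_half$log_post)
  if (n_inside == 0)
    stop_invalid("no evaluation draw inside the region; ",
                 "the covering misses the evaluation sample")
  log_v <- log(union$total_volume)
  log_inv_z <- logsumexp(-eval_half$log_post[inside]) - log(n_eval) - log_v
  diag <- list(coverage = n_inside / n_eval,
               n_ellipsoids = length(union$members))
  if (inherits(covering, "hpd_covering"))
    diag <- c(diag, covering$diagnostics)
  evidence_estimate("ecmle", -log_inv_z, log_v, n_inside, n_eval,
                    settings, diag)
}

#' Full ECMLE pipeline on a posterior sample
#'
#' Splits the draws, computes the HPD threshold at level `alpha`, builds the
#' adaptive disjoint ellipsoid covering from the construction half and
#' evaluates the estimator on the held-out half. With `cross_fit = TRUE`
#' the two halves swap roles and the two unbiased \eqn{\hat Z^{-1}} values
#' are averaged.
#'
#' @param draws a [posterior_draws()] object (2T rows).
#' @param target the [target_density()].
#' @param alpha HPD level in (0, 1]; levels around 0.75-0.80 are the stable
#'   choice on multimodal targets.
#' @param k candidate subsampling rate.
#' @param m_cap optional cap on the number of ellipsoids.
#' @param policy half-split policy, see [split_halves()].
#' @param seed seed for candidate subsampling (and a random split).
#' @param cross_fit swap halves and average the two estimates.
#' @return an [evidence_estimate()].
#' @export
ecmle_evidence <- function(draws, target, alpha = 0.75, k = 0.05,
                           m_cap = Inf, policy = "blocks", seed = NULL,
                           cross_fit = FALSE) {
  parts <- hpd_partition(draws, alpha, policy, seed)
  cfg <- covering_config(k = k, m_cap = m_cap, seed = seed)
  settings <- list(alpha = alpha, k = k, T = parts$construction$half_size * 2L,
                   seed = seed)
  one <- function(build_half, eval_half) {
    log_c <- hpd_threshold(build_half$log_post, alpha)
    part <- classify_hpd(build_half, log_c, alpha)
    cov <- build_covering(part, build_half, target, cfg)
    ecmle_estimate(cov, eval_half, settings)
  }
  est <- one(parts$construction, parts$evaluation)
  if (!cross_fit) return(est)
  cross_fit_average(est, one(parts$evaluation, parts$construction))
}

#' Average two cross-fitted estimates
#'
#' Averages on the unbiased \eqn{\hat Z^{-1}} scale (in log space) and
#' reports the absolute spread of the two \eqn{\hat Z^{-1}} values as a
#' rough variability indicator.
#'
#' @param est_ab,est_ba estimates obtained with the construction and
#'   evaluation halves swapped.
#' @return combined [evidence_estimate()].
#' @export
cross_fit_average <- function(est_ab, est_ba) {
  if (!identical(est_ab$method, est_ba$method) ||
      !identical(est_ab$settings, est_ba$settings))
    stop_invalid("cannot average estimates with different settings")
  log_inv <- logsumexp(c(est_ab$log_inv_z, est_ba$log_inv_z)) - log(2)
  m <- max(est_ab$log_inv_z, est_ba$log_inv_z)
  spread <- exp(m) * abs(exp(est_ab$log_inv_z - m) - exp(est_ba$log_inv_z - m))
  evidence_estimate(
    est_ab$method, -log_inv,
    n_eval = est_ab$n_eval, settings = est_ab$settings,
    diagnostics = list(cross_fit = TRUE, inv_z_spread = spread,
                       log_z_halves = c(est_ab$log_z, est_ba$log_z)))
}

#' Classical harmonic mean estimator
#'
#' The original instrumental-prior choice:
#' \eqn{\hat Z^{-1} = T^{-1}\sum_t 1/L(\theta_t)}. Included as a baseline;
#' its variance is unbounded for most models and that instability is the
#' documented behavior, not a defect.
#'
#' @param log_lik log-likelihood values at posterior draws.
#' @return an [evidence_estimate()].
#' @export
harmonic_mean_nr <- function(log_lik) {
  if (length(log_lik) == 0) stop_invalid("empty log-likelihood vector")
  log_inv <- logsumexp(-log_lik) - log(length(log_lik))
  evidence_estimate("hme-nr", -log_inv, n_eval = length(log_lik))
}

#' Generic Gelfand-Dey estimator
#'
#' \eqn{\hat Z^{-1} = T^{-1}\sum_t \varphi(\theta_t)/
#' (\pi(\theta_t)L(\theta_t))} for any instrumental density \eqn{\varphi}
#' normalized on the posterior support.
#'
#' @param phi_logpdf vectorized log-density of the instrumental
#'   distribution (may return `-Inf` outside its support).
#' @param theta draw matrix.
#' @param log_post log unnormalized posterior at the draws.
#' @return an [evidence_estimate()].
#' @export
gelfand_dey <- function(phi_logpdf, theta, log_post) {
  ratios <- phi_logpdf(theta) - log_post
  log_inv <- logsumexp(ratios[is.finite(ratios)]) - log(length(log_post))
  evidence_estimate("gelfand-dey", -log_inv, n_eval = length(log_post),
                    diagnostics = list(n_support = sum(is.finite(ratios))))
}

#' Gaussian and truncated-Gaussian instrumental densities
#'
#' Helpers producing vectorized log-densities for [gelfand_dey()]:
#' a Gaussian \eqn{N(\hat\theta, \hat\Sigma)}, or the same Gaussian
#' truncated to the ellipsoid
#' \eqn{(\theta-\hat\theta)^\top\hat\Sigma^{-1}(\theta-\hat\theta) < r^2},
#' whose normalizing constant is the \eqn{\chi^2_d} probability of
#' \eqn{r^2} (the quadratic form is chi-squared under the Gaussian).
#'
#' @param center,cov instrumental Gaussian mean and covariance.
#' @param r truncation radius.
#' @return a function `theta -> log phi(theta)`.
#' @export
phi_gaussian <- function(center, cov) {
  force(center); force(cov)
  function(theta) dmvnorm_log(theta, center, cov)
}

#' @rdname phi_gaussian
#' @export
phi_truncated_gaussian <- function(center, cov, r) {
  d <- length(center)
  R <- chol(cov)
  log_norm <- stats::pchisq(r^2, df = d, log.p = TRUE)
  function(theta) {
    theta <- as_matrix_rows(theta, d)
    z <- backsolve(R, t(sweep(theta, 2L, center)), transpose = TRUE)
    quad <- colSums(z^2)
    out <- dmvnorm_log(theta, center, cov) - log_norm
    out[quad >= r^2] <- -Inf
    out
  }
}

# Moment ellipsoid {quad form < r^2} from a mean and covariance, as an
# explicit `ellipsoid` (eigendecomposition gives the frame and semi-axes).
moment_ellipsoid <- function(center, cov, r) {
  eg <- eigen(cov, symmetric = TRUE)
  if (min(eg$values) <= 0)
    stop_invalid("singular covariance estimate; ",
                 "consider adding a small ridge to the diagonal")
  ellipsoid(center, eg$vectors, r * sqrt(eg$values))
}

#' Truncated harmonic mean estimator with a single Gaussian ellipsoid
#'
#' The instrumental density is uniform on the highest-density ellipsoid
#' \eqn{A = \{\theta : (\theta-\hat\theta)^\top\hat\Sigma^{-1}
#' (\theta-\hat\theta) < r^2\}} where \eqn{\hat\theta} and
#' \eqn{\hat\Sigma} are the mean and covariance of the first half of the
#' draws and the default radius is \eqn{\sqrt{d+1}} (the
#' variance-minimizing choice in the Gaussian case). The estimator is
#' evaluated on the second half.
#'
#' @param draws a [posterior_draws()] object.
#' @param r ellipsoid radius; default `sqrt(d + 1)`.
#' @param center `"mean"` (default) or `"mode"` (the maximum-log-posterior
#'   draw of the first half).
#' @return an [evidence_estimate()] whose diagnostics carry the region as
#'   an [ellipsoid()].
#' @export
thames_estimate <- function(draws, r = NULL, center = c("mean", "mode")) {
  center <- match.arg(center)
  halves <- split_halves(draws)
  first <- halves$construction; second <- halves$evaluation
  d <- ncol(first$theta)
  if (is.null(r)) r <- sqrt(d + 1)
  ctr <- if (center == "mean") colMeans(first$theta) else
    first$theta[which.max(first$log_post), ]
  e <- moment_ellipsoid(ctr, stats::cov(first$theta), r)
  inside <- ellipsoid_contains(e, second$theta)
  n_eval <- length(second$log_post)
  log_v <- log(ellipsoid_volume(e))
  if (!any(inside)) stop_invalid("no evaluation draw inside the ellipsoid")
  log_inv <- logsumexp(-second$log_post[inside]) - log(n_eval) - log_v
  evidence_estimate("thames", -log_inv, log_v, sum(inside), n_eval,
                    settings = list(r = r, center = center),
                    diagnostics = list(region = e))
}

#' HPD-truncated single-ellipsoid harmonic mean estimator
#'
#' Intersects the moment ellipsoid `A` of [thames_estimate()] with the
#' empirical HPD set \eqn{\{\theta : \pi(\theta)L(\theta) > \hat
#' q_\alpha\}}, where \eqn{\hat q_\alpha} is the empirical
#' \eqn{(1-\alpha)}-quantile of the first-half log-posterior values. The
#' intersection volume has no closed form and is estimated by Monte Carlo
#' (`n_vol` uniform draws on `A`), which makes this estimator biased
#' through the volume plug-in; the Monte Carlo volume error is reported in
#' the diagnostics. When no uniform draw survives the HPD cut, the
#' ellipsoid is re-centered at the maximum-posterior draw and the radius
#' halved, up to `max_fallback` times.
#'
#' @inheritParams thames_estimate
#' @param target the [target_density()] (needed to evaluate the HPD cut at
#'   the uniform volume draws).
#' @param alpha HPD level of the truncation.
#' @param n_vol number of uniform draws for the volume estimate.
#' @param seed RNG seed for the volume draws.
#' @param max_fallback maximum number of recenter-and-shrink retries.
#' @return an [evidence_estimate()].
#' @export
tthames_estimate <- function(draws, target, r = NULL, alpha = 0.75,
                             n_vol = 1e5, seed = NULL, max_fallback = 5) {
  halves <- split_halves(draws)
  first <- halves$construction; second <- halves$evaluation
  d <- ncol(first$theta)
  if (is.null(r)) r <- sqrt(d + 1)
  log_q <- hpd_threshold(first$log_post, alpha)
  cov1 <- stats::cov(first$theta)
  mean1 <- colMeans(first$theta)
  mode1 <- first$theta[which.max(first$log_post), ]

  for (level in 0:max_fallback) {
    ctr <- if (level == 0) mean1 else mode1
    e <- moment_ellipsoid(ctr, cov1, r / 2^level)
    u <- sample_uniform_union(e, n_vol, seed = spawn_seed(seed %||% 0, level))
    frac <- mean(target$log_post(u) > log_q)
    if (frac > 0) {
      log_v <- log(ellipsoid_volume(e)) + log(frac)
      sel <- ellipsoid_contains(e, second$theta) & second$log_post > log_q
      n_eval <- length(second$log_post)
      if (!any(sel))
        stop_invalid("no evaluation draw inside the truncated region")
      log_inv <- logsumexp(-second$log_post[sel]) - log(n_eval) - log_v
      return(evidence_estimate(
        "tthames", -log_inv, log_v, sum(sel), n_eval,
        settings = list(r = r, alpha = alpha, n_vol = n_vol, seed = seed),
        diagnostics = list(
          region = e, hit_fraction = frac, fallback_level = level,
          vol_rel_se = sqrt((1 - frac) / (frac * n_vol)))))
    }
  }
  stop_invalid("volume hit fraction zero at every fallback level; ",
               "estimation failed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition weighted kernel estimator with spherical shells
#'
#' Standardizes the draws with the first-half mean and covariance, slices
#' the standardized radius into `K` equal-width concentric shells up to
#' `r_max`, and weights each shell by a representative kernel value (the
#' unnormalized posterior at the first-half draw whose radius is nearest to
#' the shell midpoint):
#' \deqn{\hat Z^{-1} = \frac{T^{-1}\sum_t w_{k(t)}/q(\theta_t)}
#'   {\sum_k w_k V(A_k)}.}
#' The estimator is invariant to the common scale of the weights.
#'
#' @param draws a [posterior_draws()] object.
#' @param n_shells number of shells `K`.
#' @param r_max outer standardized radius of the working domain; default is
#'   the 95% quantile of the first-half standardized radii (a well-sampled
#'   region).
#' @return an [evidence_estimate()].
#' @export
pwk_estimate <- function(draws, n_shells = 10, r_max = NULL) {
  halves <- split_halves(draws)
  first <- halves$construction; second <- halves$evaluation
  d <- ncol(first$theta)
  ctr <- colMeans(first$theta)
  cov1 <- stats::cov(first$theta)
  R <- tryCatch(chol(cov1), error = function(e)
    stop_invalid("singular covariance estimate; ",
                 "consider adding a small ridge to the diagonal"))
  radius <- function(theta)
    sqrt(colSums(backsolve(R, t(sweep(theta, 2L, ctr)), transpose = TRUE)^2))
  rho1 <- radius(first$theta)
  if (is.null(r_max)) r_max <- as.numeric(stats::quantile(rho1, 0.95))
  width <- r_max / n_shells
  mids <- (seq_len(n_shells) - 0.5) * width
  log_w <- vapply(mids, function(m)
    first$log_post[which.min(abs(rho1 - m))], 1.0)

  half_log_det <- sum(log(diag(R)))
  log_vol_shell <- log(unit_ball_volume(d)) + half_log_det +
    log((seq_len(n_shells) * width)^d - ((seq_len(n_shells) - 1) * width)^d)

  rho2 <- radius(second$theta)
  shell <- pmin(pmax(ceiling(rho2 / width), 1L), n_shells)
  in_omega <- rho2 <= r_max
  n_eval <- length(second$log_post)
  if (!any(in_omega)) stop_invalid("no evaluation draw in the working domain")
  log_num <- logsumexp(log_w[shell[in_omega]] -
                       second$log_post[in_omega]) - log(n_eval)
  log_den <- logsumexp(log_w + log_vol_shell)
  evidence_estimate(
    "pwk", -(log_num - log_den), logsumexp(log_vol_shell),
    sum(in_omega), n_eval,
    settings = list(n_shells = n_shells, r_max = r_max),
    diagnostics = list(log_weights = log_w,
                       eval_per_shell = tabulate(shell[in_omega], n_shells)))
}

#' Monte Carlo variance proxy for a bounded harmonic-mean estimator
#'
#' The second moment of \eqn{\hat Z^{-1}} for a uniform-on-region
#' instrumental density reduces to a region integral of
#' \eqn{1/(\pi(\theta)L(\theta))}; a uniform Monte Carlo sample on the
#' region gives the proxy
#' \deqn{\widehat{\mathrm{proxy}} = \frac{1}{T\,V(\mathcal R)}\;
#'   \overline{1/\pi(\theta)L(\theta)},}
#' proportional to the estimator variance. Only relative comparisons
#' across HPD levels or methods are meaningful.
#'
#' @param region an [ellipsoid_union()] or [ellipsoid()] (the instrumental
#'   region).
#' @param target the [target_density()].
#' @param n_eval evaluation sample size `T` the estimator would use.
#' @param n_mc number of uniform Monte Carlo draws on the region.
#' @param seed RNG seed.
#' @return list of class `variance_proxy` with `log_proxy`, `proxy`,
#'   `rel_se` (relative Monte Carlo error) and sizes.
#' @export
variance_proxy <- function(region, target, n_eval, n_mc = 2e4, seed = NULL) {
  if (inherits(region, "ellipsoid")) region <- ellipsoid_union(list(region))
  pts <- sample_uniform_union(region, n_mc, seed)
  neg_lp <- -target$log_post(pts)
  m <- max(neg_lp)
  w <- exp(neg_lp - m)
  log_mean <- m + log(mean(w))
  structure(
    list(log_proxy = log_mean - log(n_eval) - log(region$total_volume),
         proxy = exp(log_mean - log(n_eval) - log(region$total_volume)),
         rel_se = stats::sd(w) / (mean(w) * sqrt(n_mc)),
         n_mc = n_mc, n_eval = n_eval),
    class = "variance_proxy")
}
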
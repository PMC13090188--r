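# Shared fixtures, all generated in code.

rows <- function(theta, d) {
  if (is.null(dim(theta))) matrix(theta, ncol = d, byrow = TRUE) else theta
}

# Standard isotropic Gaussian kernel under a flat prior:
# pi_tilde(theta) = exp(-||theta||^2 / 2), Z = (2 pi)^(d/2).
iso_gaussian_target <- function(d = 2) {
  target_density(
    d,
    log_post = function(theta) -0.5 * rowSums(rows(theta, d)^2),
    exact_log_evidence = (d / 2) * log(2 * pi),
    sampler = function(n, seed = NULL) withr::with_seed(
      seed, matrix(stats::rnorm(n * d), n, d)))
}

# Flat kernel pi_tilde = 1 everywhere (no normalizable evidence; used for
# exactness checks where indicator and density are both constant).
flat_target <- function(d = 2) {
  target_density(d, log_post = function(theta) rep(0, nrow(rows(theta, d))))
}

# Mixture-prior benchmark instantiated so the posterior is genuinely
# K-modal: prior modes on a circle (equal radius, so the posterior weights
# are exactly balanced), tight prior components, and a dataset centered at
# the origin.
balanced_mixture <- function(K = 2, radius = 4, spread = 0.01, n = 20,
                             seed = 42) {
  angles <- 2 * pi * (seq_len(K) - 1) / K + pi / 7
  means <- lapply(angles, function(a) radius * c(cos(a), sin(a)))
  x <- withr::with_seed(seed, matrix(stats::rnorm(n * 2), n, 2))
  x <- sweep(x, 2L, colMeans(x))            # exact zero sample mean
  mixture_prior(n = n, d = 2, weights = rep(1 / K, K), means = means,
                covs = replicate(K, spread * diag(2), simplify = FALSE),
                obs_cov = diag(2), data = x)
}

# Adaptive quadrature of exp(log_post) with a log-scale shift.
quad_log_evidence_1d <- function(log_post, lower, upper, shift,
                                 tol = 1e-12) {
  val <- stats::integrate(function(m) exp(log_post(matrix(m)) - shift),
                          lower, upper, rel.tol = tol, abs.tol = 0)$value
  log(val) + shift
}

quad_log_evidence_2d <- function(log_post, xlim, ylim, shift,
                                 tol = 1e-10) {
  inner <- function(x) vapply(x, function(xx)
    stats::integrate(function(y) exp(log_post(cbind(xx, y)) - shift),
                     ylim[1], ylim[2], rel.tol = tol, abs.tol = 0)$value,
    1.0)
  val <- stats::integrate(inner, xlim[1], xlim[2],
                          rel.tol = tol, abs.tol = 0)$value
  log(val) + shift
}
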
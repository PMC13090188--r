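#' Target density objects
#'
#' A target density bundles everything an evidence estimator needs to know
#' about a model: the dimension, a vectorized evaluator of the log
#' unnormalized posterior \eqn{\log \pi(\theta) + \log L(\theta)}, and, for
#' benchmark models, the exact log evidence and an exact posterior sampler.
#'
#' @param dim parameter dimension \eqn{d}.
#' @param log_post function taking an `n x d` matrix (or a length-`d` vector)
#'   of parameter points and returning the log unnormalized posterior at each.
#' @param exact_log_evidence optional known \eqn{\log Z}.
#' @param sampler optional function `(n, seed)` returning an `n x d` matrix of
#'   exact posterior draws.
#' @param model optional model object the density belongs to.
#' @return an object of class `ecmle_target`.
#' @export
target_density <- function(dim, log_post, exact_log_evidence = NULL,
                           sampler = NULL, model = NULL) {
  stopifnot(is.function(log_post), dim >= 1)
  structure(
    list(dim = as.integer(dim), log_post = log_post,
         exact_log_evidence = exact_log_evidence, sampler = sampler,
         model = model),
    class = "ecmle_target")
}

#' @export
print.ecmle_target <- function(x, ...) {
  cat("Target density (d =", x$dim, ")\n")
  if (!is.null(x$exact_log_evidence))
    cat("  exact log evidence:", format(x$exact_log_evidence), "\n")
  cat("  exact sampler:", if (is.null(x$sampler)) "no" else "yes", "\n")
  invisible(x)
}

#' Conjugate Gaussian benchmark model
#'
#' Observations \eqn{X_i \sim N_d(\mu, I_d)} with prior
#' \eqn{\mu \sim N_d(0, s I_d)}. The posterior is
#' \eqn{N_d(\hat m, \hat s I_d)} with \eqn{\hat m = n\bar x/(n + 1/s)} and
#' \eqn{\hat s = 1/(n + 1/s)}, and the evidence is available in closed form
#' from the standard Gaussian integral:
#' \deqn{\log Z = -\tfrac{nd}{2}\log 2\pi - \tfrac12\sum_i \|x_i\|^2
#'   - \tfrac{d}{2}\log(s\,(n + 1/s)) + \frac{n^2\|\bar x\|^2}{2(n + 1/s)}.}
#'
#' @param n number of observations (`n = 0` gives the prior alone, `Z = 1`).
#' @param d dimension.
#' @param s prior variance (positive scalar).
#' @param mu_true true mean used to simulate the dataset.
#' @param seed RNG seed for the dataset simulation.
#' @param data optional `n x d` data matrix; when supplied no simulation
#'   happens and `seed` is ignored.
#' @return list with components `data`, `model` (posterior parameters and
#'   `log_evidence`) and `target` (an [target_density()] with exact sampler).
#' @export
gaussian_conjugate <- function(n = 20, d = 2, s = 1, mu_true = rep(1, d),
                               seed = NULL, data = NULL) {
  if (s <= 0) stop_invalid("prior variance s must be positive")
  if (d < 1) stop_invalid("dimension d must be >= 1")
  if (n < 0) stop_invalid("n must be >= 0")
  stopifnot(length(mu_true) == d)
  if (is.null(data)) {
    data <- if (n > 0) {
      with_seed(seed, rmvnorm_chol(n, mu_true, diag(d)))
    } else matrix(numeric(0), 0, d)
  }
  stopifnot(nrow(data) == n, ncol(data) == d)

  xbar <- if (n > 0) colMeans(data) else rep(0, d)
  prec <- n + 1 / s
  post_mean <- n * xbar / prec
  post_var <- 1 / prec
  sumsq <- if (n > 0) sum(data^2) else 0
  log_z <- -(n * d / 2) * log(2 * pi) - sumsq / 2 -
    (d / 2) * log(s * prec) + n^2 * sum(xbar^2) / (2 * prec)

  # log prior + log likelihood, vectorized over row-points
  log_post <- function(theta) {
    theta <- as_matrix_rows(theta, d)
    ss_mu <- rowSums(theta^2)
    loglik <- -(n * d / 2) * log(2 * pi) -
      0.5 * (sumsq - 2 * n * drop(theta %*% xbar) + n * ss_mu)
    logprior <- -(d / 2) * log(2 * pi * s) - ss_mu / (2 * s)
    loglik + logprior
  }
  sampler <- function(nd, seed = NULL)
    with_seed(seed, rmvnorm_chol(nd, post_mean, post_var * diag(d)))

  model <- structure(
    list(n = n, d = d, s = s, mu_true = mu_true, xbar = xbar,
         post_mean = post_mean, post_var = post_var, log_evidence = log_z),
    class = "gaussian_conjugate")
  list(data = data, model = model,
       target = target_density(d, log_post, log_z, sampler, model))
}

#' Gaussian-mixture-prior benchmark model
#'
#' Observations \eqn{X_i \sim N_d(\mu, \Sigma_X)} with a K-component Gaussian
#' mixture prior on \eqn{\mu}. The posterior is again a K-component Gaussian
#' mixture with components \eqn{N(\hat\xi_k, \hat S_k)},
#' \eqn{\hat S_k = (n\Sigma_X^{-1} + S_k^{-1})^{-1}},
#' \eqn{\hat\xi_k = \hat S_k (n\Sigma_X^{-1}\bar x + S_k^{-1}\xi_k)}, and
#' posterior weights proportional to \eqn{\omega_k Z_k} where \eqn{Z_k} is
#' the evidence of component k. The total evidence combines the component
#' evidences with the prior weights, \eqn{Z = \sum_k \omega_k Z_k}.
#'
#' @param n number of observations (>= 1).
#' @param d dimension.
#' @param weights prior mixture weights (length K, summing to 1).
#' @param means list (or K x d matrix) of prior component means.
#' @param covs list of K prior component covariance matrices (SPD).
#' @param obs_cov observation covariance \eqn{\Sigma_X} (SPD).
#' @param seed RNG seed for the dataset simulation.
#' @param data optional `n x d` data matrix.
#' @return list with `data`, `model` (posterior mixture parameters, component
#'   evidences `log_z_k`, posterior weights `post_weights`, `log_evidence`)
#'   and `target`.
#' @export
mixture_prior <- function(n = 20, d = 2, weights = c(0.5, 0.5),
                          means = list(c(-3, -3), c(3, 3)),
                          covs = NULL, obs_cov = diag(d),
                          seed = NULL, data = NULL) {
  K <- length(weights)
  if (K < 2) stop_invalid("mixture prior needs at least 2 components")
  if (abs(sum(weights) - 1) > 1e-12)
    stop_invalid("prior weights must sum to 1")
  if (any(weights <= 0)) stop_invalid("prior weights must be positive")
  if (n < 1) stop_invalid("n must be >= 1")
  if (is.matrix(means)) means <- asplit(means, 1)
  means <- lapply(means, as.numeric)
  stopifnot(length(means) == K, all(vapply(means, length, 1L) == d))
  if (is.null(covs)) covs <- replicate(K, diag(d), simplify = FALSE)
  check_spd <- function(m, what) {
    if (!isTRUE(all.equal(m, t(m))) ||
        inherits(try(chol(m), silent = TRUE), "try-error"))
      stop_invalid(what, " must be symmetric positive definite")
  }
  for (Sk in covs) check_spd(Sk, "prior covariance")
  check_spd(obs_cov, "obs_cov")

  if (is.null(data)) {
    data <- with_seed(seed, {
      comp <- sample.int(K, 1, prob = weights)
      mu <- drop(rmvnorm_chol(1, means[[comp]], covs[[comp]]))
      rmvnorm_chol(n, mu, obs_cov)
    })
  }
  stopifnot(nrow(data) == n, ncol(data) == d)

  xbar <- colMeans(data)
  obs_prec <- solve(obs_cov)
  centered <- sweep(data, 2L, xbar)
  sw <- sum((centered %*% obs_prec) * centered)   # within-sample quadratic
  log_det <- function(m) as.numeric(determinant(m, logarithm = TRUE)$modulus)

  post_covs <- post_means <- vector("list", K)
  log_z_k <- numeric(K)
  for (k in seq_len(K)) {
    post_covs[[k]] <- solve(n * obs_prec + solve(covs[[k]]))
    post_means[[k]] <- drop(post_covs[[k]] %*%
      (n * obs_prec %*% xbar + solve(covs[[k]]) %*% means[[k]]))
    dev <- xbar - means[[k]]
    log_z_k[k] <- -(n * d / 2) * log(2 * pi) -
      ((n - 1) / 2) * log_det(obs_cov) -
      0.5 * log_det(obs_cov + n * covs[[k]]) - 0.5 * sw -
      0.5 * drop(dev %*% solve(obs_cov / n + covs[[k]], dev))
  }
  log_wz <- log(weights) + log_z_k
  log_z <- logsumexp(log_wz)
  post_weights <- exp(log_wz - log_z)

  log_post <- function(theta) {
    theta <- as_matrix_rows(theta, d)
    lp_comp <- vapply(seq_len(K), function(k)
      log(weights[k]) + dmvnorm_log(theta, means[[k]], covs[[k]]),
      numeric(nrow(theta)))
    lp_comp <- matrix(lp_comp, nrow(theta), K)
    logprior <- apply(lp_comp, 1L, logsumexp)
    dev <- sweep(theta, 2L, xbar)
    quad <- rowSums((dev %*% obs_prec) * dev)
    loglik <- -(n * d / 2) * log(2 * pi) - (n / 2) * log_det(obs_cov) -
      0.5 * (sw + n * quad)
    logprior + loglik
  }
  sampler <- function(nd, seed = NULL) {
    with_seed(seed, {
      comp <- sample.int(K, nd, replace = TRUE, prob = post_weights)
      out <- matrix(NA_real_, nd, d)
      for (k in seq_len(K)) {
        idx <- which(comp == k)
        if (length(idx))
          out[idx, ] <- rmvnorm_chol(length(idx), post_means[[k]],
                                     post_covs[[k]])
      }
      out
    })
  }

  model <- structure(
    list(n = n, d = d, K = K, weights = weights, means = means, covs = covs,
         obs_cov = obs_cov, xbar = xbar, post_weights = post_weights,
         post_means = post_means, post_covs = post_covs, log_z_k = log_z_k,
         log_evidence = log_z),
    class = "mixture_prior")
  list(data = data, model = model,
       target = target_density(d, log_post, log_z, sampler, model))
}

# Triangular Rosenbrock mean map: eta_j = mu_j(theta).
rosenbrock_forward <- function(theta, a, b) {
  theta <- as_matrix_rows(theta, length(a) + 1L)
  d <- ncol(theta)
  eta <- theta
  if (d > 1)
    eta[, -1L] <- theta[, -1L, drop = FALSE] +
      sweep(sweep(theta[, -d, drop = FALSE]^2, 2L, a), 2L, b, "*")
  eta
}

# Inverse of the forward map; unit Jacobian, solved coordinate by coordinate.
rosenbrock_inverse <- function(eta, a, b) {
  eta <- as_matrix_rows(eta, length(a) + 1L)
  d <- ncol(eta)
  theta <- eta
  for (j in seq_len(d)[-1L])
    theta[, j] <- eta[, j] - b[j - 1L] * (theta[, j - 1L]^2 - a[j - 1L])
  theta
}

#' Rosenbrock benchmark model
#'
#' A banana-shaped posterior with chained quadratic dependencies between
#' successive coordinates: sufficient statistics
#' \eqn{\bar Y_j | \theta \sim N(\mu_j(\theta), \sigma^2/n)} with
#' \eqn{\mu_1(\theta) = \theta_1} and
#' \eqn{\mu_j(\theta) = \theta_j + b_{j-1}(\theta_{j-1}^2 - a_{j-1})}, under
#' an improper flat prior on \eqn{\theta}. Because
#' \eqn{\eta = \mu(\theta)} is a triangular map with unit Jacobian, the
#' evidence is exactly 1 for every configuration, and exact posterior draws
#' are obtained by sampling \eqn{\eta_j \sim N(\bar Y_j, \sigma^2/n)}
#' independently and inverting the map.
#'
#' @param d dimension (>= 2).
#' @param n number of observations behind the sample means.
#' @param sigma observation standard deviation.
#' @param a,b length `d - 1` shape constants of the quadratic chain.
#' @param seed RNG seed used when simulating `ybar`.
#' @param ybar optional length-`d` vector of sample means; simulated from
#'   `theta_true` when missing.
#' @param theta_true parameter used to simulate `ybar`.
#' @return list with `ybar`, `model` and `target` (exact log evidence 0).
#' @export
rosenbrock <- function(d = 2, n = 20, sigma = 1, a = rep(1, d - 1),
                       b = rep(10, d - 1), seed = NULL, ybar = NULL,
                       theta_true = rep(0, d)) {
  if (d < 2) stop_invalid("Rosenbrock model needs d >= 2")
  if (sigma <= 0) stop_invalid("sigma must be positive")
  if (length(a) != d - 1 || length(b) != d - 1)
    stop_invalid("a and b must have length d - 1")
  if (is.null(ybar)) {
    stopifnot(length(theta_true) == d)
    mu <- drop(rosenbrock_forward(theta_true, a, b))
    ybar <- with_seed(seed, stats::rnorm(d, mu, sigma / sqrt(n)))
  }
  stopifnot(length(ybar) == d)

  tau2 <- sigma^2 / n
  log_post <- function(theta) {
    eta <- rosenbrock_forward(theta, a, b)
    dev <- sweep(eta, 2L, ybar)
    -(d / 2) * log(2 * pi * tau2) - rowSums(dev^2) / (2 * tau2)
  }
  sampler <- function(nd, seed = NULL) {
    eta <- with_seed(seed,
      matrix(stats::rnorm(nd * d, rep(ybar, each = nd), sqrt(tau2)), nd, d))
    rosenbrock_inverse(eta, a, b)
  }

  model <- structure(
    list(d = d, n = n, sigma = sigma, a = a, b = b, ybar = ybar),
    class = "rosenbrock")
  list(ybar = ybar, model = model,
       target = target_density(d, log_post, 0, sampler, model))
}

#' Draw an exact posterior sample from a benchmark target
#'
#' @param target an [target_density()] with an exact sampler.
#' @param n_draws total number of draws `2T` (use an even number so the
#'   sample can be split into construction and evaluation halves).
#' @param seed RNG seed.
#' @return a `posterior_draws` object: draw matrix `theta`, cached `log_post`
#'   values, `half_size` and the seed used.
#' @export
sample_posterior <- function(target, n_draws, seed = NULL) {
  stopifnot(inherits(target, "ecmle_target"))
  if (is.null(target$sampler))
    stop_invalid("target has no exact sampler; read external draws instead")
  theta <- target$sampler(n_draws, seed)
  posterior_draws(theta, target$log_post(theta),
                  origin = "exact-sampler", seed = seed)
}

#' Posterior draws container
#'
#' @param theta `2T x d` matrix of posterior draws.
#' @param log_post length-`2T` vector of log unnormalized posterior values.
#' @param origin provenance tag.
#' @param seed seed record.
#' @return object of class `posterior_draws`.
#' @export
posterior_draws <- function(theta, log_post, origin = "external", seed = NULL) {
  theta <- as.matrix(theta)
  stopifnot(nrow(theta) == length(log_post))
  structure(
    list(theta = theta, log_post = as.numeric(log_post),
         half_size = nrow(theta) %/% 2L, origin = origin, seed = seed),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", nrow(x$theta), "x", ncol(x$theta),
      "(", x$origin, ")\n")
  invisible(x)
}
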
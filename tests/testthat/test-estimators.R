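test_that("constant density on the region gives the volume exactly", {
  disk <- ellipsoid_union(list(ellipsoid(c(0, 0), diag(2), c(1, 1))))
  pts <- sample_uniform_union(disk, 500, seed = 1)
  eval_half <- posterior_draws(pts, rep(0, 500))
  est <- ecmle_estimate(disk, eval_half)
  expect_equal(est$log_z, log(pi), tolerance = 1e-12)
  expect_equal(est$n_inside, 500L)
  # zero variance: a different uniform sample gives the identical value
  pts2 <- sample_uniform_union(disk, 500, seed = 2)
  est2 <- ecmle_estimate(disk, posterior_draws(pts2, rep(0, 500)))
  expect_identical(est$log_z, est2$log_z)
})

test_that("region estimator is unbiased for 1/Z on a fixed disk", {
  tgt <- iso_gaussian_target(2)            # Z = 2*pi
  disk <- ellipsoid_union(list(ellipsoid(c(0, 0), diag(2), c(2, 2))))
  ratios <- vapply(1:200, function(i) {
    th <- tgt$sampler(500, seed = 100 + i)
    est <- ecmle_estimate(disk, posterior_draws(th, tgt$log_post(th)))
    exp(est$log_inv_z + tgt$exact_log_evidence)
  }, 1.0)
  expect_lt(abs(mean(ratios) - 1), 3 * stats::sd(ratios) / sqrt(200))
})

test_that("no-coverage and empty-input errors are raised", {
  disk <- ellipsoid_union(list(ellipsoid(c(50, 50), diag(2), c(1, 1))))
  th <- iso_gaussian_target(2)$sampler(100, seed = 4)
  eval_half <- posterior_draws(th, iso_gaussian_target(2)$log_post(th))
  expect_error(ecmle_estimate(disk, eval_half), "no evaluation draw")
  expect_error(harmonic_mean_nr(numeric(0)), "empty")
})

test_that("classical harmonic mean handles degenerate cases", {
  expect_equal(harmonic_mean_nr(rep(log(3), 50))$log_z, log(3))
  expect_equal(harmonic_mean_nr(log(7))$log_z, log(7))
})

test_that("classical harmonic mean is far noisier than the region estimator", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 5)
  lz_nr <- lz_ec <- numeric(100)
  for (i in 1:100) {
    draws <- sample_posterior(gc$target, 1000, seed = 500 + i)
    # log-likelihood = log_post minus the N(0, s I) prior term
    log_prior <- -log(2 * pi) - rowSums(draws$theta^2) / 2
    lz_nr[i] <- harmonic_mean_nr(draws$log_post - log_prior)$log_z
    lz_ec[i] <- ecmle_evidence(draws, gc$target, seed = i)$log_z
  }
  expect_gt(stats::var(lz_nr), 3 * stats::var(lz_ec))
})

test_that("Gelfand-Dey with the posterior itself has zero variance", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 6)
  phi <- phi_gaussian(gc$model$post_mean, gc$model$post_var * diag(2))
  draws <- sample_posterior(gc$target, 200, seed = 7)
  est <- gelfand_dey(phi, draws$theta, draws$log_post)
  expect_equal(est$log_z, gc$model$log_evidence, tolerance = 1e-10)
})

test_that("truncated Gaussian instrumental density is correctly normalized", {
  ctr <- c(0.5, -0.5)
  cov <- matrix(c(2, 0.5, 0.5, 1), 2)
  r <- sqrt(3)
  phi <- phi_truncated_gaussian(ctr, cov, r)
  e <- ecmle:::moment_ellipsoid(ctr, cov, r)
  u <- sample_uniform_union(e, 2e4, seed = 8)
  vals <- exp(phi(u)) * ellipsoid_volume(e)
  expect_lt(abs(mean(vals) - 1), 3 * stats::sd(vals) / sqrt(2e4))
  expect_true(all(is.infinite(phi(rbind(ctr + 100)))))
})

test_that("single-ellipsoid truncated harmonic mean uses the moment region", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 9)
  draws <- sample_posterior(gc$target, 4000, seed = 10)
  est <- thames_estimate(draws)
  expect_equal(est$settings$r, sqrt(3))
  e <- est$diagnostics$region
  # analytic region volume vs rejection sampling
  half <- e$s_max
  pts <- withr::with_seed(11, matrix(runif(4e4 * 2, -half, half), 4e4, 2))
  pts <- sweep(pts, 2L, e$center, "+")
  p_hat <- mean(ellipsoid_contains(e, pts))
  se <- sqrt(p_hat * (1 - p_hat) / 4e4) * (2 * half)^2
  expect_lt(abs(p_hat * (2 * half)^2 - ellipsoid_volume(e)), 3 * se)
  expect_error(thames_estimate(
    posterior_draws(matrix(1, 10, 2), rep(0, 10))), "singular")
})

test_that("HPD truncation reduces to the plain ellipsoid at full coverage", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 12)
  draws <- sample_posterior(gc$target, 4000, seed = 13)
  plain <- thames_estimate(draws)
  trunc <- tthames_estimate(draws, gc$target, alpha = 1, n_vol = 2e4,
                            seed = 14)
  expect_equal(trunc$log_z, plain$log_z, tolerance = 0.02)
  expect_equal(trunc$diagnostics$fallback_level, 0)
})

test_that("HPD truncation strictly shrinks the region on a bimodal target", {
  bal <- balanced_mixture(K = 2)
  draws <- sample_posterior(bal$target, 8000, seed = 15)
  est <- tthames_estimate(draws, bal$target, alpha = 0.75, n_vol = 2e4,
                          seed = 16)
  expect_lt(est$diagnostics$hit_fraction, 1)
  expect_gt(est$diagnostics$hit_fraction, 0)
})

test_that("shell-partition estimator reduces to a uniform ball at K = 1", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 17)
  draws <- sample_posterior(gc$target, 2000, seed = 18)
  est <- pwk_estimate(draws, n_shells = 1)
  halves <- split_halves(draws)
  ctr <- colMeans(halves$construction$theta)
  cv <- stats::cov(halves$construction$theta)
  ball <- ecmle:::moment_ellipsoid(ctr, cv, est$settings$r_max)
  manual <- ecmle_estimate(ellipsoid_union(list(ball)), halves$evaluation)
  expect_equal(est$log_z, manual$log_z, tolerance = 1e-9)
})

test_that("every estimator is exactly scale-equivariant in log space", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 19)
  draws <- sample_posterior(gc$target, 2000, seed = 20)
  scaled <- posterior_draws(draws$theta, draws$log_post + 5)
  tgt2 <- target_density(2, function(th) gc$target$log_post(th) + 5,
                         sampler = gc$target$sampler)
  expect_equal(ecmle_evidence(scaled, tgt2, seed = 1)$log_z,
               ecmle_evidence(draws, gc$target, seed = 1)$log_z + 5)
  expect_equal(thames_estimate(scaled)$log_z,
               thames_estimate(draws)$log_z + 5)
  expect_equal(pwk_estimate(scaled)$log_z, pwk_estimate(draws)$log_z + 5)
  expect_equal(harmonic_mean_nr(draws$log_post + 5)$log_z,
               harmonic_mean_nr(draws$log_post)$log_z + 5)
})

test_that("cross-fitted averaging combines on the unbiased scale", {
  mk <- function(log_inv) evidence_estimate("ecmle", -log_inv,
                                            settings = list(alpha = 0.75))
  a <- mk(log(2)); b <- mk(log(4))
  comb <- cross_fit_average(a, b)
  expect_equal(exp(comb$log_inv_z), 3)       # (2 + 4) / 2
  same <- cross_fit_average(a, mk(log(2)))
  expect_equal(same$log_z, a$log_z)
  bad <- evidence_estimate("ecmle", -log(4), settings = list(alpha = 0.5))
  expect_error(cross_fit_average(a, bad), "settings")

  gc <- gaussian_conjugate(n = 20, d = 2, seed = 21)
  single <- double <- numeric(60)
  for (i in 1:60) {
    draws <- sample_posterior(gc$target, 2000, seed = 700 + i)
    single[i] <- ecmle_evidence(draws, gc$target, seed = i)$log_z
    double[i] <- ecmle_evidence(draws, gc$target, seed = i,
                                cross_fit = TRUE)$log_z
  }
  # averaging the two half-swapped estimates should not inflate variance
  expect_lt(stats::var(double), 1.5 * stats::var(single))
})

test_that("variance proxy matches its closed form on a flat density", {
  disk <- ellipsoid_union(list(ellipsoid(c(0, 0), diag(2), c(1, 1))))
  px <- variance_proxy(disk, flat_target(2), n_eval = 100, n_mc = 1000,
                       seed = 22)
  expect_equal(px$proxy, 1 / (100 * pi), tolerance = 1e-12)
  expect_equal(px$rel_se, 0)
})

test_that("variance proxy Monte Carlo error shrinks at the root-n rate", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 23)
  draws <- sample_posterior(gc$target, 4000, seed = 24)
  parts <- hpd_partition(draws, 0.75)
  cov <- build_covering(parts$partition, parts$construction, gc$target,
                        covering_config(seed = 25))
  rel <- function(n_mc) mean(vapply(1:10, function(s)
    variance_proxy(cov$union, gc$target, 2000, n_mc = n_mc,
                   seed = 30 + s)$rel_se, 1.0))
  ratio <- rel(8000) / rel(2000)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)                     # ~ 1/sqrt(4) = 0.5
})
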
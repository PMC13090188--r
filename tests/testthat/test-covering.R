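test_that("candidate selection subsamples, orders and reproduces", {
  th <- withr::with_seed(1, matrix(rnorm(2000), 1000, 2))
  lp <- -rowSums(th^2) / 2
  all_sorted <- select_candidates(th, lp, k = 1)
  expect_equal(nrow(all_sorted$theta), 1000)
  expect_true(all(diff(all_sorted$log_post) <= 0))
  expect_equal(nrow(select_candidates(th, lp, k = 0.1, seed = 2)$theta), 100)
  c1 <- select_candidates(th, lp, k = 0.1, seed = 7)
  c2 <- select_candidates(th, lp, k = 0.1, seed = 7)
  expect_identical(c1$theta, c2$theta)
  expect_error(select_candidates(th[0, , drop = FALSE], numeric(0), 0.5),
               "empty HPD")
})

test_that("fitted ellipsoids recover closed-form Gaussian contours", {
  tgt <- iso_gaussian_target(2)
  hpd <- withr::with_seed(3, matrix(rnorm(400), 200, 2))
  lpd <- matrix(c(3, 0, 0, 3, -3, 0), 3, 2, byrow = TRUE)
  e <- fit_ellipsoid(c(0, 0), lpd, hpd, log_c = -2, tgt$log_post)
  expect_equal(e$semi_axes, c(2, 2), tolerance = 1e-4)

  aniso <- target_density(2, function(theta) {
    theta <- rows(theta, 2)
    -0.5 * (theta[, 1]^2 + theta[, 2]^2 / 9)
  })
  e2 <- fit_ellipsoid(c(0, 0), matrix(c(3, 0), 1, 2), hpd, -2, aniso$log_post)
  s_by_axis <- e2$semi_axes[order(abs(e2$basis[1, ]), decreasing = TRUE)]
  expect_equal(s_by_axis, c(2, 6), tolerance = 1e-4)

  # candidate sitting on the threshold yields degenerate radii
  e3 <- fit_ellipsoid(c(2, 0), matrix(c(3, 0), 1, 2), hpd, -2, tgt$log_post)
  expect_lt(max(e3$semi_axes), 1e-2)
})

test_that("three well-separated modes yield exactly three ellipsoids", {
  bal <- balanced_mixture(K = 3)
  for (s in 1:3) {
    draws <- sample_posterior(bal$target, 10000, seed = 20 + s)
    parts <- hpd_partition(draws, 0.75)
    cov <- build_covering(parts$partition, parts$construction, bal$target,
                          covering_config(k = 0.1, seed = s))
    expect_equal(cov$diagnostics$n_accepted, 3)
    # one ellipsoid per posterior mode
    centers <- t(vapply(cov$union$members, `[[`, numeric(2), "center"))
    nearest <- apply(vapply(bal$model$post_means, function(m)
      rowSums(sweep(centers, 2L, m)^2), numeric(nrow(centers))), 1L,
      which.min)
    expect_setequal(nearest, 1:3)
  }
})

test_that("accepted ellipsoids satisfy the construction contracts", {
  mx <- mixture_prior(n = 20, d = 2, seed = 7)
  draws <- sample_posterior(mx$target, 6000, seed = 8)
  parts <- hpd_partition(draws, 0.75)
  cov <- build_covering(parts$partition, parts$construction, mx$target,
                        covering_config(k = 0.05, seed = 9))
  un <- cov$union
  # centers are HPD samples at or above the threshold
  for (e in un$members)
    expect_gte(mx$target$log_post(e$center), parts$log_c)
  # pairwise disjointness re-verified post hoc
  if (length(un$members) > 1)
    for (i in seq_along(un$members)[-1]) for (j in seq_len(i - 1))
      expect_true(certify_disjoint(un$members[[i]], un$members[[j]]))
  # determinism
  cov2 <- build_covering(parts$partition, parts$construction, mx$target,
                         covering_config(k = 0.05, seed = 9))
  expect_equal(cov2$union, un)
})

test_that("unimodal covering prunes into the first ellipsoid", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 12)
  draws <- sample_posterior(gc$target, 6000, seed = 13)
  parts <- hpd_partition(draws, 0.75)
  cov <- build_covering(parts$partition, parts$construction, gc$target,
                        covering_config(k = 0.05, seed = 14))
  cand <- select_candidates(
    parts$construction$theta[parts$partition$hpd_idx, , drop = FALSE],
    parts$construction$log_post[parts$partition$hpd_idx], 0.05, seed = 14)
  expect_equal(cov$union$members[[1]]$center, unname(cand$theta[1, ]))
  expect_lte(cov$diagnostics$n_accepted, 4)
})

test_that("1-D bimodal covering endpoints sit on the threshold contour", {
  tgt <- target_density(
    1,
    log_post = function(theta) {
      th <- rows(theta, 1)[, 1]
      log(0.5 * stats::dnorm(th, -3, 0.5) + 0.5 * stats::dnorm(th, 3, 0.5))
    },
    exact_log_evidence = 0,
    sampler = function(n, seed = NULL) withr::with_seed(seed,
      matrix(stats::rnorm(n, sample(c(-3, 3), n, replace = TRUE), 0.5),
             n, 1)))
  draws <- sample_posterior(tgt, 6000, seed = 31)
  parts <- hpd_partition(draws, 0.75)
  cov <- build_covering(parts$partition, parts$construction, tgt,
                        covering_config(k = 0.05, seed = 32))
  expect_gte(cov$diagnostics$n_accepted, 2)
  expect_equal(cov$diagnostics$n_fallback_directions, 0)
  for (e in cov$union$members) {
    dev <- tgt$log_post(c(e$center - e$semi_axes, e$center + e$semi_axes)) -
      parts$log_c
    # the semi-axis is the nearer threshold crossing: one endpoint sits on
    # the contour, and neither endpoint oversteps the boundary
    expect_lt(min(abs(dev)), 1e-5)
    expect_gt(min(dev), -1e-5)
  }
})

test_that("empirical coverage of the region is sane for a unimodal target", {
  gc <- gaussian_conjugate(n = 20, d = 2, seed = 17)
  draws <- sample_posterior(gc$target, 8000, seed = 18)
  est <- ecmle_evidence(draws, gc$target, alpha = 0.75, seed = 19)
  expect_gt(est$diagnostics$coverage, 0.4)
  expect_lt(est$diagnostics$coverage, 0.9)
})
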
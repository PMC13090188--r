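#' Configuration for the adaptive ellipsoid covering
#'
#' @param k candidate subsampling rate in (0, 1]; a small fraction of the
#'   empirical HPD points is enough because accepted ellipsoids prune their
#'   interiors.
#' @param m_cap optional cap on the number of accepted ellipsoids.
#' @param tol bisection tolerance on the log-density scale.
#' @param min_axis_factor ellipsoids with any semi-axis below this fraction
#'   of the coordinate scale are discarded as degenerate (candidates sitting
#'   on the threshold).
#' @param resolution_factor ellipsoids whose largest semi-axis is below this
#'   multiple of the local inter-sample distance (the median distance from
#'   the candidate to its 10 nearest HPD neighbours) are discarded: below
#'   that scale the position of the empirical HPD boundary is dominated by
#'   sampling noise, so such ellipsoids are boundary artifacts of
#'   threshold-sitting candidates, not resolvable density structure.
#' @param seed seed for the candidate subsample.
#' @return list of class `covering_config`.
#' @export
covering_config <- function(k = 0.05, m_cap = Inf, tol = 1e-6,
                            min_axis_factor = 1e-8, resolution_factor = 1,
                            seed = NULL) {
  if (k <= 0 || k > 1) stop_invalid("subsample rate k must be in (0, 1]")
  structure(list(k = k, m_cap = m_cap, tol = tol,
                 min_axis_factor = min_axis_factor,
                 resolution_factor = resolution_factor, seed = seed),
            class = "covering_config")
}

#' Candidate center selection
#'
#' A seeded random subsample (without replacement) of the HPD points at rate
#' `k`, ordered by decreasing log-posterior so that high-density regions are
#' covered first.
#'
#' @param hpd_theta matrix of HPD points.
#' @param hpd_log_post their log unnormalized posterior values.
#' @param k subsample rate in (0, 1].
#' @param seed RNG seed.
#' @return list with ordered `theta` matrix and `log_post` vector.
#' @export
select_candidates <- function(hpd_theta, hpd_log_post, k, seed = NULL) {
  n <- nrow(hpd_theta)
  if (n == 0) stop_invalid("empty HPD set")
  m <- ceiling(k * n)
  idx <- with_seed(seed, sample.int(n, m))
  ord <- idx[order(hpd_log_post[idx], decreasing = TRUE)]
  list(theta = hpd_theta[ord, , drop = FALSE], log_post = hpd_log_post[ord])
}

# Distance from each row of pts to x.
.dist_to <- function(pts, x) sqrt(rowSums(sweep(pts, 2L, x)^2))

#' Fit a locally adapted ellipsoid at a candidate center
#'
#' The primary axis points toward the nearest low-density point (the
#' dominant direction of posterior decay); the remaining axes complete an
#' orthonormal frame by Gram-Schmidt. Each semi-axis is the smaller of the
#' two bisection radii at which the log-posterior crosses the HPD threshold
#' along the +/- axis directions, so the ellipsoid respects the nearest
#' boundary. When no crossing exists along a direction (ridges, flat tails)
#' the semi-axis falls back to the span of the HPD points projected on that
#' direction, capped at `r_cap`, and the fit is flagged.
#'
#' @param candidate length-`d` center (an HPD sample).
#' @param lpd_theta matrix of low-density points (may have zero rows).
#' @param hpd_theta matrix of HPD points (used for the fallbacks and the
#'   local bisection step).
#' @param log_c HPD threshold.
#' @param log_post vectorized log unnormalized posterior function.
#' @param bisect_cfg a [bisection_config()].
#' @return an [ellipsoid()] centered at `candidate`, with attribute
#'   `n_no_boundary` counting directions that needed the fallback.
#' @export
fit_ellipsoid <- function(candidate, lpd_theta, hpd_theta, log_c, log_post,
                          bisect_cfg = bisection_config()) {
  d <- length(candidate)
  if (nrow(lpd_theta) > 0) {
    nearest <- lpd_theta[which.min(.dist_to(lpd_theta, candidate)), ]
    u1 <- nearest - candidate
  } else {
    # alpha close to 1 leaves no LPD points: aim at the sample extreme
    centroid <- colMeans(hpd_theta)
    far <- hpd_theta[which.max(.dist_to(hpd_theta, centroid)), ]
    u1 <- far - candidate
  }
  if (sqrt(sum(u1^2)) == 0) u1 <- c(1, rep(0, d - 1))

  # local length scale: median distance to the 10 nearest HPD neighbours
  dd <- sort(.dist_to(hpd_theta, candidate))
  dd <- dd[dd > 0]
  local_scale <- if (length(dd))
    max(stats::median(dd[seq_len(min(10, length(dd)))]), 1e-12) else 1e-12
  bisect_cfg$init_step <- local_scale

  U <- orthonormal_basis(u1)
  centered <- sweep(hpd_theta, 2L, candidate)
  n_fallback <- 0L
  one_side <- function(dir_vec, i) {
    r <- boundary_radius(candidate, dir_vec, log_c, log_post, bisect_cfg)
    if (is.na(r)) {
      n_fallback <<- n_fallback + 1L
      span <- max(abs(centered %*% U[, i]))
      r <- min(max(span, bisect_cfg$tol), bisect_cfg$r_cap)
    }
    r
  }
  s <- vapply(seq_len(d), function(i)
    min(one_side(U[, i], i), one_side(-U[, i], i)), 1.0)
  structure(ellipsoid(candidate, U, pmax(s, .Machine$double.xmin)),
            n_no_boundary = n_fallback, local_scale = local_scale)
}

#' Build the disjoint ellipsoid covering of an empirical HPD region
#'
#' Candidate centers are processed in order of decreasing posterior density.
#' Each candidate is fitted with [fit_ellipsoid()]; the tentative ellipsoid
#' is accepted only if its bounding sphere is disjoint from every accepted
#' member, after which all remaining candidates inside it are pruned.
#' Construction stops when candidates are exhausted or `m_cap` is reached.
#'
#' @param partition an `hpd_partition` of the construction half (see
#'   [classify_hpd()]).
#' @param draws_half the construction-half `posterior_draws`.
#' @param target the [target_density()] (its `log_post` drives the boundary
#'   searches).
#' @param cfg a [covering_config()].
#' @return object of class `hpd_covering`: the [ellipsoid_union()] `union`
#'   plus `diagnostics` (candidate counts, rejections, fallback flags).
#' @export
build_covering <- function(partition, draws_half, target,
                           cfg = covering_config()) {
  stopifnot(inherits(partition, "hpd_partition"))
  hpd_theta <- draws_half$theta[partition$hpd_idx, , drop = FALSE]
  hpd_lp <- draws_half$log_post[partition$hpd_idx]
  lpd_theta <- draws_half$theta[partition$lpd_idx, , drop = FALSE]
  if (nrow(hpd_theta) == 0) stop_invalid("empty HPD set")

  coord_scale <- max(apply(draws_half$theta, 2L, function(x) diff(range(x))))
  bis <- bisection_config(tol = cfg$tol, r_cap = 10 * max(coord_scale, 1e-12))
  min_axis <- cfg$min_axis_factor * max(coord_scale, 1e-12)

  cand <- select_candidates(hpd_theta, hpd_lp, cfg$k, cfg$seed)
  active <- rep(TRUE, nrow(cand$theta))
  accepted <- list()
  n_overlap <- n_degenerate <- n_fallback_dirs <- 0L

  for (i in seq_along(active)) {
    if (!active[i]) next
    if (length(accepted) >= cfg$m_cap) break
    e <- fit_ellipsoid(cand$theta[i, ], lpd_theta, hpd_theta,
                       partition$log_c, target$log_post, bis)
    active[i] <- FALSE
    if (any(e$semi_axes < min_axis) ||
        max(e$semi_axes) < cfg$resolution_factor * attr(e, "local_scale")) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    overlap <- any(vapply(accepted, function(a) !certify_disjoint(a, e),
                          logical(1)))
    if (overlap) {
      n_overlap <- n_overlap + 1L
      next
    }
    n_fallback_dirs <- n_fallback_dirs + attr(e, "n_no_boundary")
    accepted[[length(accepted) + 1L]] <- e
    if (any(active))
      active[active] <- !ellipsoid_contains(
        e, cand$theta[active, , drop = FALSE])
  }
  if (length(accepted) == 0)
    stop_invalid("no ellipsoid accepted: ", nrow(cand$theta),
                 " candidates, ", n_degenerate, " degenerate, ",
                 n_overlap, " overlap-rejected")

  structure(
    list(union = ellipsoid_union(accepted),
         diagnostics = list(
           alpha = partition$alpha, log_c = partition$log_c,
           n_candidates = nrow(cand$theta),
           n_accepted = length(accepted),
           n_rejected_overlap = n_overlap,
           n_degenerate = n_degenerate,
           n_fallback_directions = n_fallback_dirs),
         config = cfg),
    class = "hpd_covering")
}

#' @export
print.hpd_covering <- function(x, ...) {
  d <- x$diagnostics
  cat("HPD covering (alpha =", d$alpha, "):", d$n_accepted,
      "ellipsoid(s) from", d$n_candidates, "candidates\n",
      " total volume", format(x$union$total_volume),
      "| overlap-rejected", d$n_rejected_overlap,
      "| degenerate", d$n_degenerate, "\n")
  invisible(x)
}
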
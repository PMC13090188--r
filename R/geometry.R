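unit_ball_volume <- function(d) pi^(d / 2) / gamma(d / 2 + 1)

#' Ellipsoid objects
#'
#' An ellipsoid is parameterized by its center \eqn{\mu}, a `d x d` matrix
#' `basis` with orthonormal columns, and positive semi-axis lengths `s`;
#' the induced shape matrix is \eqn{\Sigma = U\,diag(s^2)\,U^\top} and the
#' ellipsoid is \eqn{\{\theta : (\theta-\mu)^\top\Sigma^{-1}(\theta-\mu)
#' \le 1\}} (boundary inclusive).
#'
#' @param center length-`d` center.
#' @param basis `d x d` matrix with orthonormal columns.
#' @param semi_axes length-`d` positive semi-axis lengths.
#' @return object of class `ellipsoid`.
#' @export
ellipsoid <- function(center, basis, semi_axes) {
  d <- length(center)
  basis <- matrix(basis, d, d)
  stopifnot(length(semi_axes) == d)
  if (any(semi_axes <= 0)) stop_invalid("semi-axes must be positive")
  if (max(abs(crossprod(basis) - diag(d))) > 1e-8)
    stop_invalid("basis columns are not orthonormal")
  structure(
    list(center = as.numeric(center), basis = basis,
         semi_axes = as.numeric(semi_axes), s_max = max(semi_axes)),
    class = "ellipsoid")
}

#' @rdname ellipsoid
#' @param e an `ellipsoid`.
#' @export
shape_matrix <- function(e) {
  e$basis %*% diag(e$semi_axes^2, length(e$semi_axes)) %*% t(e$basis)
}

#' Analytic ellipsoid volume
#'
#' \eqn{V = \pi^{d/2}/\Gamma(d/2+1)\prod_i s_i
#'    = \pi^{d/2}/\Gamma(d/2+1)\sqrt{\det\Sigma}}.
#'
#' @param e an [ellipsoid()].
#' @return the volume.
#' @export
ellipsoid_volume <- function(e) {
  unit_ball_volume(length(e$center)) * prod(e$semi_axes)
}

#' Ellipsoid and union membership
#'
#' Quadratic-form test \eqn{\sum_i (\langle u_i, \theta-\mu\rangle/s_i)^2
#' \le 1}; the boundary counts as inside.
#'
#' @param e an [ellipsoid()] or [ellipsoid_union()].
#' @param theta a length-`d` point or an `n x d` matrix of row-points.
#' @return logical vector of memberships.
#' @export
ellipsoid_contains <- function(e, theta) {
  if (inherits(e, "ellipsoid_union")) {
    hits <- rep(FALSE, nrow(as_matrix_rows(theta, length(e$members[[1]]$center))))
    for (m in e$members) hits <- hits | ellipsoid_contains(m, theta)
    return(hits)
  }
  theta <- as_matrix_rows(theta, length(e$center))
  proj <- sweep(theta, 2L, e$center) %*% e$basis
  rowSums(sweep(proj, 2L, e$semi_axes, "/")^2) <= 1 + 1e-9
}

#' Bounding-sphere disjointness certificate
#'
#' Sufficient condition for two ellipsoids not to intersect: the distance
#' between their centers is at least the sum of their maximum semi-axes.
#'
#' @param e1,e2 ellipsoids of the same dimension.
#' @return `TRUE` when the certificate holds.
#' @export
certify_disjoint <- function(e1, e2) {
  sqrt(sum((e1$center - e2$center)^2)) >= e1$s_max + e2$s_max
}

#' Disjoint union of ellipsoids
#'
#' Validates the pairwise bounding-sphere certificate and caches the exact
#' total volume (the sum of member volumes, valid because members are
#' disjoint).
#'
#' @param members list of [ellipsoid()] objects.
#' @param check re-verify pairwise disjointness (default `TRUE`).
#' @return object of class `ellipsoid_union` with `members` and
#'   `total_volume`.
#' @export
ellipsoid_union <- function(members, check = TRUE) {
  if (length(members) == 0) stop_invalid("empty ellipsoid union")
  if (check && length(members) > 1) {
    for (i in seq_along(members)[-1]) for (j in seq_len(i - 1))
      if (!certify_disjoint(members[[i]], members[[j]]))
        stop_invalid("members ", j, " and ", i,
                     " fail the disjointness certificate")
  }
  structure(
    list(members = members,
         total_volume = sum(vapply(members, ellipsoid_volume, 1.0))),
    class = "ellipsoid_union")
}

#' @export
print.ellipsoid_union <- function(x, ...) {
  cat("Ellipsoid union:", length(x$members), "member(s), total volume",
      format(x$total_volume), "\n")
  invisible(x)
}

#' Orthonormal basis with a prescribed first direction
#'
#' Gram-Schmidt completion: the remaining columns are seeded from the
#' standard basis vectors least parallel to `u1`.
#'
#' @param u1 a nonzero length-`d` vector (normalized internally).
#' @return `d x d` matrix with orthonormal columns, first column
#'   proportional to `u1`.
#' @export
orthonormal_basis <- function(u1) {
  nrm <- sqrt(sum(u1^2))
  if (nrm == 0) stop_invalid("zero direction vector")
  u1 <- u1 / nrm
  d <- length(u1)
  if (d == 1) return(matrix(u1, 1, 1))
  # drop the standard basis vector most parallel to u1, keep the rest
  seeds <- order(abs(u1))[seq_len(d - 1)]
  U <- matrix(0, d, d)
  U[, 1] <- u1
  col <- 1L
  for (j in seeds) {
    v <- numeric(d); v[j] <- 1
    v <- v - U[, seq_len(col), drop = FALSE] %*%
      crossprod(U[, seq_len(col), drop = FALSE], v)
    # re-orthogonalize once for numerical safety
    v <- v - U[, seq_len(col), drop = FALSE] %*%
      crossprod(U[, seq_len(col), drop = FALSE], v)
    col <- col + 1L
    U[, col] <- v / sqrt(sum(v^2))
  }
  U
}

#' Bisection search for the HPD boundary along a ray
#'
#' Finds the radius `r` at which the log unnormalized posterior along
#' `center + r * direction/||direction||` crosses the threshold `log_c`:
#' a doubling expansion brackets the crossing, then bisection refines it to
#' `tol` on the log-density scale.
#'
#' @param center point with `log_post(center) >= log_c`.
#' @param direction nonzero search direction.
#' @param log_c HPD threshold (log scale).
#' @param log_post vectorized log unnormalized posterior function.
#' @param cfg list of numerical controls, see [bisection_config()].
#' @return the radius, or `NA` with attribute `no_boundary = TRUE` when the
#'   density never crosses `log_c` within `r_cap`.
#' @export
boundary_radius <- function(center, direction, log_c, log_post,
                            cfg = bisection_config()) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop_invalid("zero direction vector")
  u <- direction / nrm
  g <- function(r) log_post(center + r * u) - log_c
  if (g(0) < -cfg$tol) stop_invalid("center lies below the HPD threshold")

  r_lo <- 0
  r_hi <- min(cfg$init_step, cfg$r_cap)
  expand <- 0L
  while (g(r_hi) >= 0) {
    if (r_hi >= cfg$r_cap || expand >= cfg$max_expand)
      return(structure(NA_real_, no_boundary = TRUE))
    r_lo <- r_hi
    r_hi <- min(2 * r_hi, cfg$r_cap)
    expand <- expand + 1L
  }
  for (i in seq_len(cfg$max_iter)) {
    mid <- (r_lo + r_hi) / 2
    gm <- g(mid)
    if (abs(gm) <= cfg$tol || (r_hi - r_lo) < 1e-14 * max(1, r_hi)) break
    if (gm >= 0) r_lo <- mid else r_hi <- mid
  }
  (r_lo + r_hi) / 2
}

#' Numerical controls for the boundary bisection
#'
#' @param tol convergence tolerance on the log-density scale.
#' @param init_step initial bracketing step (callers typically reset it to a
#'   local inter-point distance scale).
#' @param max_expand maximum number of bracket doublings.
#' @param r_cap hard cap on the search radius.
#' @param max_iter maximum bisection iterations.
#' @return list of controls.
#' @export
bisection_config <- function(tol = 1e-6, init_step = 1, max_expand = 60,
                             r_cap = Inf, max_iter = 200) {
  list(tol = tol, init_step = init_step, max_expand = max_expand,
       r_cap = r_cap, max_iter = max_iter)
}

#' Uniform sampling on a disjoint ellipsoid union
#'
#' A member is chosen with probability proportional to its volume; within a
#' member, a uniform unit-ball draw is scaled by the semi-axes and rotated
#' by the basis.
#'
#' @param union an [ellipsoid_union()] (a single [ellipsoid()] is accepted).
#' @param n number of points.
#' @param seed RNG seed.
#' @return `n x d` matrix of points, all inside the union.
#' @export
sample_uniform_union <- function(union, n, seed = NULL) {
  if (inherits(union, "ellipsoid")) union <- ellipsoid_union(list(union))
  stopifnot(inherits(union, "ellipsoid_union"))
  d <- length(union$members[[1]]$center)
  vols <- vapply(union$members, ellipsoid_volume, 1.0)
  with_seed(seed, {
    member <- sample.int(length(vols), n, replace = TRUE, prob = vols)
    z <- matrix(stats::rnorm(n * d), n, d)
    z <- z / sqrt(rowSums(z^2)) * stats::runif(n)^(1 / d)  # uniform unit ball
    out <- matrix(NA_real_, n, d)
    for (k in seq_along(union$members)) {
      idx <- which(member == k)
      if (!length(idx)) next
      e <- union$members[[k]]
      pts <- sweep(z[idx, , drop = FALSE], 2L, e$semi_axes, "*") %*% t(e$basis)
      out[idx, ] <- sweep(pts, 2L, e$center, "+")
    }
    out
  })
}

#' Serialize / restore an ellipsoid union as JSON
#'
#' Stores centers, basis columns, semi-axes and the total volume so an
#' evaluation run can be repeated without reconstructing the covering.
#'
#' @param union an [ellipsoid_union()].
#' @param path file path.
#' @return `union_from_json` returns the restored [ellipsoid_union()].
#' @export
union_to_json <- function(union, path) {
  members <- lapply(union$members, function(e)
    list(center = e$center, basis = as.numeric(e$basis),
         semi_axes = e$semi_axes))
  jsonlite::write_json(
    list(dimension = length(union$members[[1]]$center), members = members,
         total_volume = union$total_volume),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname union_to_json
#' @export
union_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dimension
  members <- lapply(seq_len(nrow(obj$members)), function(i)
    ellipsoid(unlist(obj$members$center[i]),
              matrix(unlist(obj$members$basis[i]), d, d),
              unlist(obj$members$semi_axes[i])))
  ellipsoid_union(members)
}
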
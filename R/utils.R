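#' @keywords internal
"_PACKAGE"

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run expr under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched. seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible sub-seed from a master seed; fixed arithmetic so
# adding replications never perturbs earlier ones. Stays within 32-bit range.
spawn_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483629)
}

# n draws from N_d(mean, cov) as an n x d matrix (chol parameterization).
rmvnorm_chol <- function(n, mean, cov) {
  d <- length(mean)
  L <- chol(cov)                      # upper triangular, cov = t(L) %*% L
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% L, 2L, mean, "+")
}

# Log N_d(x; mean, cov) for each row of x (n x d matrix).
dmvnorm_log <- function(x, mean, cov) {
  x <- as_matrix_rows(x, length(mean))
  L <- chol(cov)
  z <- backsolve(L, t(sweep(x, 2L, mean)), transpose = TRUE)
  -0.5 * length(mean) * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

# Accept a vector (one point) or matrix of row-points; return n x d matrix.
as_matrix_rows <- function(theta, d) {
  if (is.null(dim(theta))) {
    stopifnot(length(theta) %% d == 0)
    theta <- matrix(theta, ncol = d, byrow = TRUE)
  }
  stopifnot(ncol(theta) == d)
  theta
}

stop_invalid <- function(...) stop(..., call. = FALSE)
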
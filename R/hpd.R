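#' Split posterior draws into construction and evaluation halves
#'
#' Unbiasedness of the truncated estimators requires the instrumental region
#' to be built from draws that are not reused in the estimator average. The
#' default policy keeps the two contiguous blocks (first T / last T rows),
#' which respects MCMC time ordering; `policy = "random"` applies a seeded
#' permutation, appropriate for i.i.d. draws.
#'
#' @param draws a [posterior_draws()] object with an even number of rows.
#' @param policy `"blocks"` or `"random"`.
#' @param seed permutation seed (only used for `policy = "random"`).
#' @return list of two `posterior_draws` halves named `construction` and
#'   `evaluation`.
#' @export
split_halves <- function(draws, policy = c("blocks", "random"), seed = NULL) {
  policy <- match.arg(policy)
  n <- nrow(draws$theta)
  if (n < 4) stop_invalid("need at least 4 draws to split")
  if (n %% 2L != 0L)
    stop_invalid("odd number of draws; drop one row before splitting")
  idx <- seq_len(n)
  if (policy == "random") idx <- with_seed(seed, sample.int(n))
  first <- idx[seq_len(n %/% 2L)]
  second <- idx[(n %/% 2L + 1L):n]
  half <- function(i) posterior_draws(draws$theta[i, , drop = FALSE],
                                      draws$log_post[i],
                                      origin = draws$origin, seed = draws$seed)
  list(construction = half(first), evaluation = half(second))
}

#' Empirical HPD threshold
#'
#' Order-statistic convention: the \eqn{\lceil \alpha T \rceil} draws with
#' the largest log unnormalized posterior values form the empirical HPD set,
#' and the threshold \eqn{\log c} is the smallest of those values (the
#' empirical \eqn{(1-\alpha)}-quantile of the log-posterior values, without
#' interpolation).
#'
#' @param log_post numeric vector of log unnormalized posterior values.
#' @param alpha HPD level in (0, 1].
#' @return the threshold `log_c`.
#' @export
hpd_threshold <- function(log_post, alpha) {
  if (length(log_post) == 0) stop_invalid("empty log-posterior vector")
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must be in (0, 1]")
  m <- ceiling(alpha * length(log_post))
  sort(log_post, decreasing = TRUE)[m]
}

#' Classify a half-sample into high- and low-density index sets
#'
#' Draws with `log_post >= log_c` are the empirical HPD points (ties at the
#' threshold count as HPD); the rest are the low posterior density (LPD)
#' points.
#'
#' @param draws_half a `posterior_draws` half-sample.
#' @param log_c threshold from [hpd_threshold()].
#' @param alpha the level the threshold was computed at (recorded).
#' @return object of class `hpd_partition` with `hpd_idx`, `lpd_idx`,
#'   `log_c` and `alpha`.
#' @export
classify_hpd <- function(draws_half, log_c, alpha = NA_real_) {
  stopifnot(is.finite(log_c))
  hpd_idx <- which(draws_half$log_post >= log_c)
  structure(
    list(alpha = alpha, log_c = log_c, hpd_idx = hpd_idx,
         lpd_idx = which(draws_half$log_post < log_c),
         n = length(draws_half$log_post)),
    class = "hpd_partition")
}

#' Algorithm step 1: split, threshold and classify in one call
#'
#' @param draws a [posterior_draws()] object.
#' @param alpha HPD level in (0, 1].
#' @inheritParams split_halves
#' @return list with the two halves, the `hpd_partition` of the construction
#'   half, and `log_c`.
#' @export
hpd_partition <- function(draws, alpha, policy = "blocks", seed = NULL) {
  halves <- split_halves(draws, policy, seed)
  log_c <- hpd_threshold(halves$construction$log_post, alpha)
  list(construction = halves$construction, evaluation = halves$evaluation,
       partition = classify_hpd(halves$construction, log_c, alpha),
       log_c = log_c)
}

#' @export
print.hpd_partition <- function(x, ...) {
  cat("HPD partition: alpha =", x$alpha, " log c =", format(x$log_c),
      "\n  HPD:", length(x$hpd_idx), "draws; LPD:", length(x$lpd_idx),
      "draws\n")
  invisible(x)
}
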
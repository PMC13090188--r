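#' Read and write posterior draw files
#'
#' Draws are exchanged as CSV with header
#' `theta_1,...,theta_d,log_post`, one row per draw, '.' decimal
#' separator; numeric values are written with 17 significant digits so a
#' round trip is lossless.
#'
#' @param draws a [posterior_draws()] object.
#' @param path file path.
#' @param target optional [target_density()]; when given, the stored
#'   `log_post` column is validated against it (tolerance `1e-10`).
#' @return `read_draws_csv` returns a [posterior_draws()] object;
#'   `write_draws_csv` returns `path` invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  d <- ncol(draws$theta)
  header <- paste(c(paste0("theta_", seq_len(d)), "log_post"), collapse = ",")
  body <- apply(cbind(draws$theta, draws$log_post), 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_draws_csv
#' @export
read_draws_csv <- function(path, target = NULL) {
  tab <- utils::read.csv(path, header = TRUE)
  cols <- grep("^theta_", names(tab))
  if (length(cols) == 0 || !"log_post" %in% names(tab))
    stop_invalid("draws file must have columns theta_1..theta_d, log_post")
  theta <- as.matrix(tab[, cols, drop = FALSE])
  lp <- tab$log_post
  if (!is.null(target)) {
    recomputed <- target$log_post(theta)
    if (max(abs(recomputed - lp)) > 1e-10 * pmax(1, max(abs(lp))))
      stop_invalid("stored log_post disagrees with the target density")
  }
  posterior_draws(theta, lp, origin = "external-file")
}

#' Serialize an evidence estimate as JSON
#'
#' @param est an [evidence_estimate()].
#' @param path optional path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
estimate_to_json <- function(est, path = NULL) {
  payload <- list(
    method = est$method, log_z_hat = est$log_z, inv_z_hat = est$inv_z,
    log_region_volume = est$log_region_volume, n_inside = est$n_inside,
    n_eval = est$n_eval, settings = est$settings,
    diagnostics = est$diagnostics[!vapply(
      est$diagnostics, function(x) inherits(x, "ellipsoid"), logical(1))])
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null", na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Load an experiment configuration from YAML
#'
#' Keys mirror the [experiment_config()] arguments, with the model under
#' `model:` (keys `name`, `d`, `n`, `sigma`, `s`, `a`, `b`, `weights`,
#' `means`, `covs`, `obs_cov`, `ybar`, `seed`).
#'
#' @param path YAML file path.
#' @param seed optional master-seed override.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$model)) stop_invalid("config needs a 'model' block")
  experiment_config(
    model = y$model,
    methods = unlist(y$methods) %||% "ecmle",
    alpha = y$alpha %||% 0.75,
    n_draws = y$n_draws %||% 20000,
    M = y$M %||% 100,
    k = y$k %||% 0.05,
    n_vol = y$n_vol %||% 2e4,
    fixed_data = y$fixed_data %||% TRUE,
    seed = seed %||% y$seed %||% 1)
}
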
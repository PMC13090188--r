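#' Experiment configuration
#'
#' Describes a replication experiment: a benchmark model, the estimators to
#' run, their settings and the draw budget. One master seed spawns
#' per-replication sub-seeds by fixed arithmetic, so increasing `M` never
#' perturbs earlier replications.
#'
#' @param model model spec: a list with `name` (`"gaussian"`, `"mixture"`
#'   or `"rosenbrock"`) plus the model parameters accepted by
#'   [gaussian_conjugate()], [mixture_prior()] or [rosenbrock()].
#' @param methods character vector among `"ecmle"`, `"thames"`,
#'   `"tthames"`, `"pwk"`, `"gd-gaussian"`.
#' @param alpha HPD level used by the HPD-based methods.
#' @param n_draws total posterior draws `2T` per replication.
#' @param M number of replications.
#' @param k ECMLE candidate subsampling rate.
#' @param n_vol Monte Carlo volume draws for the HPD-truncated
#'   single-ellipsoid method.
#' @param fixed_data if `TRUE` one dataset is simulated once and reused in
#'   every replication (only the posterior sample is redrawn); if `FALSE`
#'   each replication simulates a fresh dataset.
#' @param seed master seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(model, methods = "ecmle", alpha = 0.75,
                              n_draws = 20000, M = 100, k = 0.05,
                              n_vol = 2e4, fixed_data = TRUE, seed = 1) {
  stopifnot(n_draws >= 4, M >= 1)
  methods <- match.arg(methods,
    c("ecmle", "thames", "tthames", "pwk", "gd-gaussian"),
    several.ok = TRUE)
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must be in (0, 1]")
  structure(list(model = model, methods = methods, alpha = alpha,
                 n_draws = as.integer(n_draws), M = as.integer(M), k = k,
                 n_vol = n_vol, fixed_data = isTRUE(fixed_data),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Instantiate a benchmark model from a spec list
#'
#' @param spec list with `name` and model parameters.
#' @param seed dataset simulation seed (overrides `spec$seed`).
#' @return the list returned by the model constructor (`data`/`ybar`,
#'   `model`, `target`).
#' @export
build_model <- function(spec, seed = NULL) {
  name <- match.arg(spec$name, c("gaussian", "mixture", "rosenbrock"))
  seed <- seed %||% spec$seed
  grab <- function(key, default) spec[[key]] %||% default
  switch(name,
    gaussian = gaussian_conjugate(
      n = grab("n", 20), d = grab("d", 2), s = grab("s", 1),
      mu_true = unlist(grab("mu_true", rep(1, grab("d", 2)))), seed = seed),
    mixture = {
      d <- grab("d", 2)
      means <- grab("means", list(c(-3, -3), c(3, 3)))
      if (!is.list(means)) means <- asplit(matrix(unlist(means),
                                                  ncol = d, byrow = TRUE), 1)
      covs <- grab("covs", NULL)
      if (!is.null(covs))
        covs <- lapply(covs, function(m) matrix(unlist(m), d, d))
      obs_cov <- grab("obs_cov", diag(d))
      if (!is.matrix(obs_cov)) obs_cov <- matrix(unlist(obs_cov), d, d)
      mixture_prior(n = grab("n", 20), d = d,
                    weights = unlist(grab("weights", c(0.5, 0.5))),
                    means = means, covs = covs, obs_cov = obs_cov,
                    seed = seed)
    },
    rosenbrock = {
      d <- grab("d", 2)
      rosenbrock(d = d, n = grab("n", 20), sigma = grab("sigma", 1),
                 a = unlist(grab("a", rep(1, d - 1))),
                 b = unlist(grab("b", rep(10, d - 1))),
                 ybar = if (!is.null(spec$ybar)) unlist(spec$ybar),
                 seed = seed)
    })
}

#' Run one estimator on a posterior sample
#'
#' Thin dispatcher used by the experiment drivers and the CLI.
#'
#' @param draws a [posterior_draws()] object.
#' @param target the [target_density()].
#' @param method one of `"ecmle"`, `"thames"`, `"tthames"`, `"pwk"`,
#'   `"gd-gaussian"`.
#' @param alpha HPD level for the HPD-based methods.
#' @param k ECMLE candidate subsampling rate.
#' @param n_vol Monte Carlo volume draws for `"tthames"`.
#' @param seed RNG seed for the stochastic construction steps.
#' @return an [evidence_estimate()].
#' @export
estimate_evidence <- function(draws, target, method = "ecmle", alpha = 0.75,
                              k = 0.05, n_vol = 2e4, seed = NULL) {
  switch(method,
    ecmle = ecmle_evidence(draws, target, alpha = alpha, k = k, seed = seed),
    thames = thames_estimate(draws),
    tthames = tthames_estimate(draws, target, alpha = alpha, n_vol = n_vol,
                               seed = seed),
    pwk = pwk_estimate(draws),
    `gd-gaussian` = {
      halves <- split_halves(draws)
      phi <- phi_gaussian(colMeans(halves$construction$theta),
                          stats::cov(halves$construction$theta))
      gelfand_dey(phi, halves$evaluation$theta, halves$evaluation$log_post)
    },
    stop_invalid("unknown method: ", method))
}

#' Run a replication experiment
#'
#' For each replication: simulate (or reuse) the dataset, draw a fresh
#' exact posterior sample, run every configured method, and record the
#' estimate. Individual replication failures are recorded with `NA`
#' estimates and the error message, not raised.
#'
#' @param cfg an [experiment_config()].
#' @return data.frame of replication records: `replication`, `method`,
#'   `alpha`, `log_z_hat`, `ratio` (\eqn{\hat Z/Z} when the exact evidence
#'   is known), `n_inside`, `n_ellipsoids`, `runtime`, `error`.
#' @export
run_replications <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  fixed <- if (cfg$fixed_data) build_model(cfg$model,
                                           seed = spawn_seed(cfg$seed, 0))
  rows <- vector("list", cfg$M * length(cfg$methods))
  r <- 0L
  for (i in seq_len(cfg$M)) {
    rep_seed <- spawn_seed(cfg$seed, i)
    inst <- if (cfg$fixed_data) fixed else
      build_model(cfg$model, seed = spawn_seed(rep_seed, 1))
    draws <- sample_posterior(inst$target, cfg$n_draws,
                              seed = spawn_seed(rep_seed, 2))
    for (m in cfg$methods) {
      r <- r + 1L
      t0 <- proc.time()[["elapsed"]]
      est <- tryCatch(
        estimate_evidence(draws, inst$target, m, alpha = cfg$alpha,
                          k = cfg$k, n_vol = cfg$n_vol,
                          seed = spawn_seed(rep_seed, 3)),
        error = function(e) e)
      dt <- proc.time()[["elapsed"]] - t0
      failed <- inherits(est, "error")
      lz <- if (failed) NA_real_ else est$log_z
      exact <- inst$target$exact_log_evidence
      rows[[r]] <- data.frame(
        replication = i, method = m, alpha = cfg$alpha,
        log_z_hat = lz,
        ratio = if (!is.null(exact) && !failed) exp(lz - exact) else NA_real_,
        n_inside = if (failed) NA_integer_ else est$n_inside %||% NA_integer_,
        n_ellipsoids = if (!failed && !is.null(est$diagnostics$n_ellipsoids))
          est$diagnostics$n_ellipsoids else NA_integer_,
        runtime = dt,
        error = if (failed) conditionMessage(est) else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the HPD level
#'
#' Runs [run_replications()] at each level of `alpha_grid` (same master
#' seed, so datasets and draws coincide across levels) and additionally
#' evaluates the Monte Carlo variance proxy of the constructed region at
#' each level.
#'
#' @param cfg an [experiment_config()].
#' @param alpha_grid HPD levels in (0, 1].
#' @param proxy_reps number of independent proxy evaluations per level.
#' @param proxy_n_mc uniform Monte Carlo draws per proxy evaluation.
#' @return list with `records` (stacked replication tables) and `proxies`
#'   (data.frame `alpha`, `rep`, `log_proxy`).
#' @export
alpha_sweep <- function(cfg, alpha_grid = c(0.10, 0.25, 0.50, 0.75, 0.80,
                                            0.90, 0.99),
                        proxy_reps = 3, proxy_n_mc = 2e4) {
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid > 0 & alpha_grid <= 1))
  records <- do.call(rbind, lapply(alpha_grid, function(a) {
    cfg_a <- cfg; cfg_a$alpha <- a
    run_replications(cfg_a)
  }))
  proxies <- do.call(rbind, lapply(alpha_grid, function(a) {
    do.call(rbind, lapply(seq_len(proxy_reps), function(s) {
      sd0 <- spawn_seed(cfg$seed, 100000 + s)
      inst <- build_model(cfg$model, seed = spawn_seed(cfg$seed, 0))
      draws <- sample_posterior(inst$target, cfg$n_draws, seed = sd0)
      parts <- hpd_partition(draws, a)
      cov <- build_covering(parts$partition, parts$construction, inst$target,
                            covering_config(k = cfg$k, seed = sd0))
      px <- variance_proxy(cov$union, inst$target,
                           n_eval = parts$evaluation$half_size * 2L,
                           n_mc = proxy_n_mc, seed = spawn_seed(sd0, 7))
      data.frame(alpha = a, rep = s, log_proxy = px$log_proxy)
    }))
  }))
  list(records = records, proxies = proxies)
}

#' Summarize replication records
#'
#' Groups by method and level and reports mean, standard deviation and
#' quartiles (linear-interpolation quantiles, R type 7) of the log evidence
#' and of the evidence ratio when available.
#'
#' @param records data.frame from [run_replications()].
#' @return summary data.frame, one row per method x alpha.
#' @export
summarize_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop_invalid("empty records")
  groups <- split(records, list(records$method, records$alpha), drop = TRUE)
  do.call(rbind, lapply(groups, function(g) {
    lz <- g$log_z_hat[!is.na(g$log_z_hat)]
    rt <- g$ratio[!is.na(g$ratio)]
    q <- stats::quantile(lz, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      method = g$method[1], alpha = g$alpha[1], n = nrow(g),
      n_failed = sum(is.na(g$log_z_hat)),
      mean_log_z = mean(lz),
      sd_log_z = if (length(lz) > 1) stats::sd(lz) else 0,
      q25_log_z = q[1], median_log_z = q[2], q75_log_z = q[3],
      mean_ratio = if (length(rt)) mean(rt) else NA_real_,
      se_ratio = if (length(rt) > 1) stats::sd(rt) / sqrt(length(rt))
                 else NA_real_,
      stringsAsFactors = FALSE)
  }))
}
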
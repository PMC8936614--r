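#' Gelman-Rubin convergence diagnostic
#'
#' Potential-scale-reduction factor per group-level parameter, computed
#' from between-chain (B) and within-chain (W) variances:
#' `Rhat = sqrt(((n - 1) / n * W + B / n) / W)`. Values near 1 indicate
#' that the chains have mixed; the conventional convergence criterion for
#' this analysis is `Rhat < 1.01` for every group-level parameter.
#'
#' @param samples A `ddm_posterior` (>= 2 chains, >= 10 retained draws
#'   each), or a list of draw matrices with common columns.
#' @param params Parameters to diagnose (default: group-level).
#' @return Named vector of Rhat values.
#' @export
gelman_rubin <- function(samples, params = NULL) {
  if (inherits(samples, "ddm_posterior")) {
    params <- params %||% samples$group_params
    chains <- lapply(samples$chains, function(d) d[, params, drop = FALSE])
  } else {
    chains <- lapply(samples, as.matrix)
    params <- params %||% colnames(chains[[1]])
    chains <- lapply(chains, function(d) d[, params, drop = FALSE])
  }
  m <- length(chains)
  if (m < 2) stop("Gelman-Rubin needs at least 2 chains")
  n <- min(vapply(chains, nrow, 0L))
  if (n < 10) stop("need at least 10 retained draws per chain")
  chains <- lapply(chains, function(d) d[seq_len(n), , drop = FALSE])
  out <- vapply(seq_along(params), function(j) {
    means <- vapply(chains, function(d) mean(d[, j]), numeric(1))
    vars <- vapply(chains, function(d) var(d[, j]), numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(out) <- params
  out
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` where `D(theta) = -2 loglik`, `Dbar` is the posterior
#' mean deviance over retained draws and `pD = Dbar - D(theta_bar)` the
#' effective parameter count, with `theta_bar` the posterior mean of the
#' participant-level parameters. Lower is better.
#'
#' @param samples A `ddm_posterior`.
#' @param table The behaviour table the model was fitted to.
#' @param spec The [ddm_spec()] used (defaults to the one in `samples`).
#' @return List with `dic`, `dbar`, `d_at_mean`, `pd`.
#' @export
dic <- function(samples, table, spec = samples$spec) {
  pool <- pooled_draws(samples)
  dbar <- mean(pool[, "deviance"])
  theta_bar <- colMeans(pool)
  d_idx <- which(spec$blocks == "drift")
  n_idx <- which(spec$blocks == "ndt")
  b_idx <- which(spec$blocks == "boundary")
  ll <- 0
  for (cl in samples$cells) {
    sub <- table[table$condition == cl$cond &
                   table$participant == cl$participant, ]
    th <- theta_bar[paste0(spec$coef_names, "_", cl$cond, "_p",
                           cl$participant)]
    drift <- drop(block_design(sub, spec$drift) %*% th[d_idx])
    ndt <- drop(block_design(sub, spec$ndt) %*% th[n_idx])
    bound <- drop(block_design(sub, spec$boundary) %*% th[b_idx])
    lli <- .ddm_loglik_cpp(sub$rt, as.integer(sub$accuracy), drift, ndt,
                           bound, samples$meta$w, 1e-6)
    if (!is.finite(lli))
      stop("likelihood not finite at the posterior mean; ",
           "inspect convergence for ", cl$cond, "/p", cl$participant)
    ll <- ll + lli
  }
  d_at_mean <- -2 * ll
  pd <- dbar - d_at_mean
  list(dic = dbar + pd, dbar = dbar, d_at_mean = d_at_mean, pd = pd)
}

#' Posterior probability of an expression over group-level parameters
#'
#' Evaluates an inequality (or any logical expression) over pooled draws,
#' e.g. `"mu_gamma1_VH > mu_gamma1_V"` or `"mu_gamma1_VH - mu_gamma1_V >
#' 0"`, returning the fraction of retained draws (pooled across chains)
#' satisfying it. Parameter names follow `posterior_summary()`.
#'
#' @param samples A `ddm_posterior`.
#' @param expression Character scalar or unevaluated expression.
#' @return Probability in \[0, 1\].
#' @export
posterior_prob <- function(samples, expression) {
  pool <- pooled_draws(samples)
  env <- as.data.frame(pool)
  ex <- if (is.character(expression)) parse(text = expression)[[1]]
        else expression
  used <- all.vars(ex)
  unknown <- setdiff(used, colnames(pool))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  val <- eval(ex, envir = env)
  if (!is.logical(val)) stop("expression must evaluate to a logical vector")
  mean(val)
}
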
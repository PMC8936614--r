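#' Sample the posterior of the hierarchical drift-diffusion model
#'
#' Joint posterior over participant-level regression coefficients and
#' group-level (per condition) means and standard deviations, with
#' single-trial drift, nondecision time and boundary assembled from the
#' behaviour table per the regression specification and the likelihood
#' given by the Wiener first-passage-time density (accuracy coding, upper
#' boundary = correct, starting point fixed at the midpoint).
#'
#' Hierarchy: `coef[participant, condition] ~ N(mu[condition],
#' sigma[condition]^2)` with uniform hyperpriors on box supports (drift
#' coefficients (-20, 20); boundary intercept (0.1, 10); nondecision-time
#' intercept (0.05, min observed RT); other coefficients (-10, 10); group
#' SDs (0.005, 5)).
#'
#' The sampler is adaptive Metropolis-within-Gibbs: each participant-level
#' coefficient gets a Gaussian random-walk proposal whose scale is tuned
#' during burn-in toward ~35% acceptance, group means are updated by exact
#' (truncated-normal) Gibbs draws and group SDs by a log-scale random walk.
#' Adaptation is frozen after burn-in. Chains run sequentially with
#' seed-derived substreams, so identical inputs give identical draws.
#'
#' @param table QC-filtered behaviour table with `participant`, `condition`,
#'   `rt`, `accuracy` and every covariate named in `spec`.
#' @param spec A [ddm_spec()].
#' @param chains Number of chains (default 3).
#' @param n_samples Total iterations per chain (default 5500).
#' @param burn Burn-in iterations discarded (default 500).
#' @param thin Thinning factor applied after burn-in (default 50).
#' @param seed Integer seed.
#' @param w Starting-point fraction (fixed, default 0.5).
#' @param eps Wiener density series tolerance.
#' @param interweave_every Apply the non-centred interweaved group moves
#'   every this many iterations (1 = every iteration; larger values trade
#'   mixing for speed).
#' @return A `ddm_posterior` object: per-chain draw matrices over group and
#'   participant parameters plus deviance, parameter names, spec and
#'   sampler metadata.
#' @export
sample_posterior <- function(table, spec, chains = 3, n_samples = 5500,
                             burn = 500, thin = 50, seed = 1L, w = 0.5,
                             eps = 1e-6, interweave_every = 1L) {
  stopifnot(inherits(spec, "ddm_spec"), burn < n_samples, thin >= 1)
  need <- c("participant", "condition", "rt", "accuracy")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  conds <- unique(table$condition)
  p <- length(spec$coef_names)
  d_idx <- which(spec$blocks == "drift")
  n_idx <- which(spec$blocks == "ndt")
  b_idx <- which(spec$blocks == "boundary")
  min_rt <- min(table$rt)
  bounds <- coef_bounds(spec, min_rt)

  # per participant x condition cell: data and design blocks
  cells <- list()
  for (cond in conds) {
    for (pp in unique(table$participant[table$condition == cond])) {
      sub <- table[table$condition == cond & table$participant == pp, ]
      cells[[length(cells) + 1L]] <- list(
        cond = cond, cond_i = match(cond, conds), participant = pp,
        rt = sub$rt, acc = as.integer(sub$accuracy),
        Xd = block_design(sub, spec$drift),
        Xn = block_design(sub, spec$ndt),
        Xb = block_design(sub, spec$boundary),
        min_rt = min(sub$rt))
    }
  }
  ncell <- length(cells)
  nc <- length(conds)

  cell_ll <- function(cell, th) {
    drift <- drop(cell$Xd %*% th[d_idx])
    ndt <- drop(cell$Xn %*% th[n_idx])
    bound <- drop(cell$Xb %*% th[b_idx])
    .ddm_loglik_cpp(cell$rt, cell$acc, drift, ndt, bound, w, eps)
  }

  # concatenated data for the compiled sweep
  rt_all <- unlist(lapply(cells, `[[`, "rt"))
  acc_all <- unlist(lapply(cells, `[[`, "acc"))
  off <- cumsum(c(0L, vapply(cells, function(cl) length(cl$rt), 0L)))
  Xd_all <- do.call(rbind, lapply(cells, `[[`, "Xd"))
  Xn_all <- do.call(rbind, lapply(cells, `[[`, "Xn"))
  Xb_all <- do.call(rbind, lapply(cells, `[[`, "Xb"))
  block_id <- c(rep(0L, length(d_idx)), rep(1L, length(n_idx)),
                rep(2L, length(b_idx)))
  block_col <- c(seq_along(d_idx), seq_along(n_idx), seq_along(b_idx)) - 1L
  cond_of_all <- vapply(cells, function(cl) cl$cond_i, 0L)
  n_per_cond <- as.vector(table(factor(cond_of_all, levels = seq_len(nc))))
  # per-block intercept position (0-based within the coefficient vector)
  int_idx <- vapply(list(spec$drift, spec$ndt, spec$boundary), function(cv) {
    k <- which(cv == "1")
    if (length(k)) k[1] - 1L else -1L
  }, 0L)
  int_idx <- int_idx + c(0L, length(d_idx), length(d_idx) + length(n_idx)) *
    (int_idx >= 0)
  # cell-specific covariate means used by the centred joint moves
  col_means <- matrix(0, ncell, p)
  for (i in seq_len(ncell)) {
    col_means[i, ] <- c(colMeans(cells[[i]]$Xd), colMeans(cells[[i]]$Xn),
                        colMeans(cells[[i]]$Xb))
  }

  nkeep <- floor((n_samples - burn) / thin)
  group_names <- c(outer(spec$coef_names, conds,
                         function(a, b) paste0("mu_", a, "_", b)),
                   outer(spec$coef_names, conds,
                         function(a, b) paste0("sigma_", a, "_", b)))
  part_names <- unlist(lapply(cells, function(cl)
    paste0(spec$coef_names, "_", cl$cond, "_p", cl$participant)))
  all_names <- c(group_names, part_names, "deviance")

  chain_draws <- vector("list", chains)
  accept_info <- numeric(chains)

  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, "chain", ch))
    # dispersed but likelihood-feasible starts
    theta <- matrix(0, ncell, p)
    for (i in seq_len(ncell)) {
      for (j in seq_len(p)) {
        blk <- spec$blocks[j]; cv <- spec$covariates[j]
        init <- if (blk == "drift" && cv == "1") 0.5
        else if (blk == "ndt" && cv == "1") 0.3 * cells[[i]]$min_rt
        else if (blk == "boundary" && cv == "1") 2
        else 0
        jit <- rnorm(1, 0, 0.03 * (1 + 0.5 * ch))
        val <- init * (1 + jit) + if (init == 0) jit else 0
        theta[i, j] <- min(max(val, bounds$lower[j] + 1e-6),
                           min(bounds$upper[j],
                               if (blk == "ndt" && cv == "1")
                                 0.8 * cells[[i]]$min_rt else Inf) - 1e-6)
      }
    }
    mu <- matrix(0, nc, p); sig <- matrix(0, nc, p)
    for (ci in seq_len(nc)) {
      idx <- which(vapply(cells, function(cl) cl$cond_i, 0L) == ci)
      mu[ci, ] <- colMeans(theta[idx, , drop = FALSE])
      sig[ci, ] <- pmax(0.15 * abs(mu[ci, ]), 0.1)
    }
    ll <- vapply(seq_len(ncell),
                 function(i) cell_ll(cells[[i]], theta[i, ]), numeric(1))
    # cells whose jittered start is infeasible (e.g. a negative trial ndt)
    # fall back to the safe configuration: zero slopes, conservative
    # intercepts, which always has finite likelihood
    for (i in which(!is.finite(ll))) {
      for (j in seq_len(p)) {
        blk <- spec$blocks[j]; cv <- spec$covariates[j]
        theta[i, j] <- if (blk == "drift" && cv == "1") 0.5
        else if (blk == "ndt" && cv == "1") 0.3 * cells[[i]]$min_rt
        else if (blk == "boundary" && cv == "1") 2
        else 0
      }
      ll[i] <- cell_ll(cells[[i]], theta[i, ])
    }
    if (any(!is.finite(ll)))
      stop("could not initialise sampler at finite likelihood")

    th_scale <- matrix(0.08, ncell, p)
    th_scale[, intersect(seq_len(p), which(spec$blocks == "ndt" &
                                             spec$covariates == "1"))] <- 0.04
    sig_scale <- matrix(0.3, nc, p)
    th_scale2 <- matrix(0.08, ncell, p)
    mu_iscale <- matrix(0.1, nc, p)
    sig_iscale <- matrix(0.3, nc, p)
    acc_n <- matrix(0, ncell, p)
    acc_n2 <- matrix(0, ncell, p)
    acc_imu <- matrix(0, nc, p)
    acc_isig <- matrix(0, nc, p)
    iw_n <- 0
    sig_acc <- matrix(0, nc, p)
    window_n <- 0
    cond_fac <- factor(cond_of_all, levels = seq_len(nc))

    draws <- matrix(NA_real_, nkeep, length(all_names))
    colnames(draws) <- all_names
    keep_i <- 0L
    total_acc <- 0; total_try <- 0

    for (it in seq_len(n_samples)) {
      # participant-level coefficients (compiled sweep)
      res <- .ddm_sweep_cpp(theta, ll, rt_all, acc_all, off,
                            Xd_all, Xn_all, Xb_all, cond_of_all, mu, sig,
                            bounds$lower, bounds$upper, th_scale,
                            block_id, block_col, w, eps,
                            th_scale2, int_idx, col_means)
      theta <- res$theta; ll <- res$ll
      acc_n <- acc_n + res$accepts
      acc_n2 <- acc_n2 + res$accepts2
      total_acc <- total_acc + sum(res$accepts)
      total_try <- total_try + ncell * p
      window_n <- window_n + 1

      # group-level updates, vectorised over condition x coefficient
      th_mean <- rowsum(theta, cond_fac) / n_per_cond
      sdv <- sig / sqrt(n_per_cond)
      plo <- pnorm(matrix(bounds$lower, nc, p, byrow = TRUE), th_mean, sdv)
      phi <- pnorm(matrix(bounds$upper, nc, p, byrow = TRUE), th_mean, sdv)
      u <- matrix(runif(nc * p), nc, p)
      mu <- qnorm(plo + u * (phi - plo), th_mean, sdv)
      mu <- pmin(pmax(mu, matrix(bounds$lower, nc, p, byrow = TRUE)),
                 matrix(bounds$upper, nc, p, byrow = TRUE))

      ss <- rowsum((theta - mu[cond_of_all, , drop = FALSE])^2, cond_fac)
      s_new <- sig * exp(matrix(rnorm(nc * p), nc, p) * sig_scale)
      lr <- (1 - n_per_cond) * log(s_new / sig) -
        ss / 2 * (1 / s_new^2 - 1 / sig^2)
      ok <- s_new > 0.005 & s_new < 5 &
        matrix(log(runif(nc * p)), nc, p) < lr
      sig[ok] <- s_new[ok]
      sig_acc <- sig_acc + ok

      # interweaved non-centred group moves (every other iteration): break
      # the funnel coupling between group SDs and participant coefficients
      if (it %% interweave_every == 0) {
        iw <- .ddm_interweave_cpp(theta, ll, rt_all, acc_all, off,
                                  Xd_all, Xn_all, Xb_all, cond_of_all,
                                  mu, sig, bounds$lower, bounds$upper,
                                  mu_iscale, sig_iscale,
                                  block_id, block_col, w, eps)
        theta <- iw$theta; ll <- iw$ll; mu <- iw$mu; sig <- iw$sig
        acc_imu <- acc_imu + iw$acc_mu
        acc_isig <- acc_isig + iw$acc_sig
        iw_n <- iw_n + 1
      }

      # proposal adaptation during burn-in only
      if (it <= burn && it %% 25 == 0) {
        rate <- acc_n / window_n
        th_scale <- pmin(pmax(th_scale * exp(0.8 * (rate - 0.35)), 1e-4), 5)
        rate2 <- acc_n2 / window_n
        th_scale2 <- pmin(pmax(th_scale2 * exp(0.8 * (rate2 - 0.35)), 1e-4), 5)
        srate <- sig_acc / window_n
        sig_scale <- pmin(pmax(sig_scale * exp(0.8 * (srate - 0.35)), 0.01), 3)
        if (iw_n > 0) {
          mu_iscale <- pmin(pmax(mu_iscale *
            exp(0.8 * (acc_imu / iw_n - 0.35)), 1e-4), 5)
          sig_iscale <- pmin(pmax(sig_iscale *
            exp(0.8 * (acc_isig / iw_n - 0.35)), 0.01), 3)
        }
        acc_n[] <- 0; acc_n2[] <- 0; sig_acc[] <- 0
        acc_imu[] <- 0; acc_isig[] <- 0; window_n <- 0; iw_n <- 0
      }
      if (it > burn && (it - burn) %% thin == 0 && keep_i < nkeep) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- c(as.vector(t(mu)), as.vector(t(sig)),
                             as.vector(t(theta)), -2 * sum(ll))
      }
    }
    chain_draws[[ch]] <- draws[seq_len(keep_i), , drop = FALSE]
    accept_info[ch] <- total_acc / total_try
  }

  structure(list(chains = chain_draws,
                 param_names = all_names,
                 group_params = group_names,
                 spec = spec, conditions = conds,
                 cells = lapply(cells, function(cl)
                   cl[c("cond", "participant")]),
                 meta = list(n_chains = chains, n_samples = n_samples,
                             burn = burn, thin = thin, seed = seed,
                             acceptance = accept_info, w = w)),
            class = "ddm_posterior")
}

#' Pooled draws of a posterior
#'
#' @param samples A `ddm_posterior`.
#' @return Matrix of draws pooled across chains.
#' @export
pooled_draws <- function(samples) {
  do.call(rbind, samples$chains)
}

#' Posterior summary table
#'
#' Mean, 5% and 95% quantiles and the Gelman-Rubin statistic for every
#' group-level parameter, in the layout used for reporting core DDM
#' parameter estimates.
#'
#' @param samples A `ddm_posterior`.
#' @return Data frame with columns `parameter`, `mean`, `ci5`, `ci95`,
#'   `rhat`.
#' @export
posterior_summary <- function(samples) {
  pool <- pooled_draws(samples)
  rh <- gelman_rubin(samples)
  data.frame(parameter = samples$group_params,
             mean = colMeans(pool[, samples$group_params, drop = FALSE]),
             ci5 = apply(pool[, samples$group_params, drop = FALSE], 2,
                         quantile, 0.05),
             ci95 = apply(pool[, samples$group_params, drop = FALSE], 2,
                          quantile, 0.95),
             rhat = rh[samples$group_params],
             row.names = NULL)
}
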
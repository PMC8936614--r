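test_that("the first-passage density is a proper two-boundary density", {
  dens <- function(t, v, a, up) exp(wfpt_logpdf(t, v, a, 0.5, upper = up))
  # total probability across both boundaries on a (drift, boundary) grid
  for (v in c(-2, 0, 2)) {
    for (a in c(0.5, 1, 2)) {
      tot <- integrate(function(t) dens(t, v, a, TRUE) + dens(t, v, a, FALSE),
                       0, Inf, rel.tol = 1e-8)$value
      expect_equal(tot, 1, tolerance = 1e-4)
    }
  }
  # absorption probability against the closed form
  pu <- integrate(function(t) dens(t, 1, 2, TRUE), 0, Inf)$value
  expect_equal(pu, 0.8808, tolerance = 1e-3)
  # invalid arguments
  expect_error(wfpt_logpdf(1, 1, -1), "boundary")
  expect_error(wfpt_logpdf(1, 1, 1, w = 0), "w must")
  expect_error(wfpt_logpdf(1, 1, 1, eps = 1), "eps")
  expect_identical(wfpt_logpdf(-1, 1, 2), -Inf)
})

test_that("density matches the Euler-Maruyama simulation oracle", {
  v <- 0.5; a <- 1.5
  sim <- simulate_behavior(v, a, seed = 99, n = 30000, dt = 5e-4)
  up <- sim$rt[sim$choice == "upper"]
  # CDF of upper-boundary decision times from the density, on a grid
  grid <- quantile(up, seq(0.02, 0.98, by = 0.02))
  p_up <- integrate(function(t) exp(wfpt_logpdf(t, v, a, upper = TRUE)),
                    0, Inf)$value
  cdf_th <- vapply(grid, function(g)
    integrate(function(t) exp(wfpt_logpdf(t, v, a, upper = TRUE)),
              0, g)$value / p_up, numeric(1))
  cdf_emp <- vapply(grid, function(g) mean(up <= g), numeric(1))
  expect_lt(max(abs(cdf_th - cdf_emp)), 0.02)
})

test_that("trial log likelihood honours accuracy coding and boundaries", {
  expect_identical(trial_loglik(1, 1, 1, 2, ndt = 1), -Inf)  # rt == ndt
  # zero drift: identical likelihood for correct and error at equal rt
  expect_equal(trial_loglik(1.4, 1, 0, 2, ndt = 0.2),
               trial_loglik(1.4, 0, 0, 2, ndt = 0.2))
  # grid-scan oracle: summed loglik is maximised near the generating drift
  gen <- simulate_behavior(0.8, 2, ndt = 0.3, seed = 21, n = 3000)
  acc <- as.integer(gen$choice == "upper")
  grid <- seq(0.2, 1.6, by = 0.05)
  ll <- vapply(grid, function(v)
    sum(trial_loglik(gen$rt, acc, v, 2, ndt = 0.3)), numeric(1))
  expect_lt(abs(grid[which.max(ll)] - 0.8), 0.15)
})

test_that("the regression spec validates covariates and names coefficients", {
  sp <- ddm_spec()
  expect_identical(sp$coef_names,
                   c("gamma0", "gamma1", "beta0", "beta_sw", "beta_exp",
                     "alpha"))
  expect_error(ddm_spec(drift = c("1", "r2_s", "r2_s")), "duplicate")
  expect_error(ddm_spec(drift = c("1", "bogus")), "unknown")
  expect_error(ddm_spec(drift = "r2_s"), "intercept")
  expect_length(candidate_models(), 7L)
})

test_that("posterior sampling is deterministic and shaped as configured", {
  fit <- small_ddm_fit()
  expect_length(fit$chains, 2L)
  expect_equal(nrow(fit$chains[[1]]), (2000 - 700) %/% 10)
  fit2 <- sample_posterior(small_behavior(), ddm_spec(), chains = 2,
                           n_samples = 2000, burn = 700, thin = 10, seed = 5)
  expect_identical(fit$chains, fit2$chains)
  no_rt <- small_behavior()[, setdiff(names(small_behavior()), "rt")]
  expect_error(sample_posterior(no_rt, ddm_spec()), "lacks|column")
})

test_that("hierarchical estimates recover truth and exhibit shrinkage", {
  fit <- small_ddm_fit()
  ps <- posterior_summary(fit)
  g1 <- ps[ps$parameter == "mu_gamma1_VH", ]
  expect_gt(g1$ci95, 2); expect_lt(g1$ci5, 4.5)
  expect_gt(posterior_prob(fit, "mu_gamma1_VH > 0"), 0.9)

  # shrinkage: participant-level posterior means lie between the group mean
  # and the participant's own no-pooling estimate (allowing MCMC jitter)
  pool <- pooled_draws(fit)
  tab <- small_behavior()
  grp <- mean(pool[, "mu_alpha_VH"])
  between <- vapply(sort(unique(tab$participant)), function(pp) {
    post <- mean(pool[, paste0("alpha_VH_p", pp)])
    sub <- tab[tab$participant == pp, ]
    th <- colMeans(pool[, paste0(fit$spec$coef_names, "_VH_p", pp)])
    names(th) <- fit$spec$coef_names
    nopool <- optimize(function(a) {
      drift <- th["gamma0"] + th["gamma1"] * sub$r2 * sub$s
      ndt <- th["beta0"] + th["beta_sw"] * sub$n_cr + th["beta_exp"] * sub$t_low
      sum(trial_loglik(sub$rt, sub$accuracy, drift, a, ndt))
    }, c(0.5, 8), maximum = TRUE)$maximum
    lo <- min(grp, nopool) - 0.1; hi <- max(grp, nopool) + 0.1
    post >= lo && post <= hi
  }, logical(1))
  expect_gte(mean(between), 0.7)
})

test_that("gelman_rubin flags non-convergence and passes identical chains", {
  # duplicated chains: Rhat ~ 1
  set.seed(1)
  d <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_lt(max(abs(gelman_rubin(list(d, d)) - 1)), 0.01)
  # disjoint supports: Rhat >> 1.1
  d2 <- d; d2[, 1] <- d2[, 1] + 100
  expect_gt(gelman_rubin(list(d, d2))[["a"]], 5)
  expect_error(gelman_rubin(list(d)), "2 chains")

  # independent oracle: coda's PSRF on AR(1)-correlated chains
  set.seed(3)
  mk <- function() matrix(as.vector(arima.sim(list(ar = 0.6), 300)) +
                            rnorm(1, 0, 0.2), ncol = 1,
                          dimnames = list(NULL, "x"))
  chains <- list(mk(), mk(), mk())
  ours <- gelman_rubin(chains)[["x"]]
  ref <- coda::gelman.diag(coda::as.mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$psrf[1, 1]
  # coda adds a sampling-variability df correction on top of the classic
  # PSRF, so agreement is approximate
  expect_equal(ours, ref, tolerance = 0.05)
})

test_that("posterior_prob evaluates expressions over group draws", {
  fit <- small_ddm_fit()
  expect_equal(posterior_prob(fit, "mu_gamma1_VH > mu_gamma1_VH"), 0)
  p <- posterior_prob(fit, "mu_alpha_VH - mu_alpha_VH >= 0")
  expect_equal(p, 1)
  expect_error(posterior_prob(fit, "mu_nonexistent > 0"), "unknown")
})

test_that("dic penalises complexity and rewards the generating structure", {
  fit <- small_ddm_fit()
  tab <- small_behavior()
  d <- dic(fit, tab)
  expect_true(is.finite(d$dic))
  expect_gt(d$pd, 0)
  # adding a pure-noise covariate to the boundary raises pD
  over_spec <- ddm_spec(c("1", "r2_s"), c("1", "n_cr", "t_low"),
                        c("1", "r2"), name = "overparameterised")
  fit_over <- sample_posterior(tab, over_spec,
                               chains = 2, n_samples = 2000, burn = 700,
                               thin = 10, seed = 5)
  d_over <- dic(fit_over, tab)
  expect_gt(d_over$pd, d$pd * 0.8)
  # identical models give identical DIC
  d2 <- dic(small_ddm_fit(), tab)
  expect_equal(d$dic, d2$dic)
})
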
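test_that("copula normalisation yields standard-normal marginals", {
  set.seed(1)
  x <- rnorm(1e4)
  z <- copula_normalize(x)
  expect_gt(cor(x, z), 0.99)          # Gaussian input passes ~unchanged
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(var(z) - 1), 0.05)
  # rank invariance under monotone transforms
  expect_equal(copula_normalize(exp(x)), z)
  expect_error(copula_normalize(1:5), "10 samples")
  expect_warning(copula_normalize(rep(c(1, 2), 50)), "tied|degenerate")
})

test_that("gaussian MI matches the closed form across correlations", {
  set.seed(7)
  n <- 1e5
  for (rho in c(0, 0.3, 0.5, 0.8)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    mi <- gaussian_mi(x, y)
    expect_lt(abs(mi - (-0.5 * log2(1 - rho^2))), 0.01)
  }
  x <- rnorm(1e4)
  expect_error(gaussian_mi(x, x), "singular")
})

test_that("co-information matches analytic Gaussian cases", {
  set.seed(11)
  n <- 1e5
  V <- rnorm(n); H <- rnorm(n); eps <- rnorm(n)
  target <- V + H + eps
  # closed form: 2 * 0.5 log2(3/2) - 0.5 log2(3) = -0.2075 (net synergy)
  expect_equal(co_information(target, V, H), -0.2075, tolerance = 0.01)
  # irrelevant third variable
  t2 <- V + 0.5 * rnorm(n)
  expect_equal(co_information(t2, V, H), 0, tolerance = 0.01)
  # shared copy: co-information equals the single MI (pure redundancy)
  Hc <- V + 1e-4 * rnorm(n)
  expect_equal(co_information(t2, V, Hc), gaussian_mi(t2, V),
               tolerance = 0.02)
})

test_that("the CCS decomposition produces the expected dominant atoms", {
  set.seed(3)
  n <- 1e5
  V <- rnorm(n); H <- rnorm(n)
  # target coupled only to V: unique-V dominates
  tV <- V + rnorm(n)
  res <- pid_ccs(tV, V, H)
  expect_equal(res$uniq_v, res$mi_v, tolerance = 0.02)
  expect_lt(abs(res$red), 0.02)
  expect_lt(abs(res$syn), 0.02)
  expect_lt(abs(res$uniq_h), 0.02)

  # duplicated predictor: pure redundancy
  Hd <- V + 0.01 * rnorm(n)
  res2 <- pid_ccs(tV, V, Hd)
  expect_equal(res2$red, res2$mi_v, tolerance = 0.05)
  expect_lt(abs(res2$uniq_v), 0.05)
  expect_lt(res2$syn, 0.05)

  # lattice identities hold to numerical precision on arbitrary input
  t3 <- V + H + rnorm(n)
  res3 <- pid_ccs(t3, V, H)
  expect_equal(res3$red + res3$uniq_v + res3$uniq_h + res3$syn,
               res3$mi_joint, tolerance = 1e-9)
  expect_equal(res3$red + res3$uniq_v, res3$mi_v, tolerance = 1e-9)
  expect_equal(res3$red + res3$uniq_h, res3$mi_h, tolerance = 1e-9)

  # invariance to monotone transforms of each input
  res4 <- pid_ccs(exp(t3), V^3, H)
  expect_equal(res4$red, res3$red, tolerance = 1e-6)

  # mmi fallback bounds redundancy by the smaller single MI
  res5 <- pid_ccs(t3, V, H, estimator = "mmi")
  expect_equal(res5$red, min(res5$mi_v, res5$mi_h))

  expect_error(pid_ccs(V, V, H, normalize = FALSE), "singular")
})

test_that("channel-wise PID identifies constructed interaction structure", {
  # build V/H/VH conditions where one channel's VH kernel copies the V
  # kernel (unique-V channel) and EEG is otherwise independent noise
  fs <- 50
  spec <- lag_spec(fs = fs)
  cfg <- sim_config(n_participants = 1, n_trials_per_cell = 4,
                    conditions = c("V", "H", "VH"), fs = fs, n_channels = 4,
                    trial_duration = 3, coupling_snr = c(V = 2, H = 2, VH = 2),
                    seed = 55)
  pat_v <- make_forward_pattern(4, fs, seed = 1)
  pat_h <- make_forward_pattern(4, fs, seed = 2)
  pat_vh <- pat_v                      # channel kernels copy V exactly
  mk_trials <- function(pat, snr, base_seed) lapply(1:12, function(k) {
    tr <- simulate_trajectory(cfg, 3, seed = base_seed + k)
    v <- compute_velocity(tr); attr(v, "fs") <- fs
    list(eeg = simulate_eeg(v, pat, snr = snr, seed = 1000 + base_seed + k),
         velocity = v, trial = k)
  })
  trials_v <- mk_trials(pat_v, 2, 100)
  trials_h <- mk_trials(pat_h, 2, 200)
  trials_vh <- mk_trials(pat_vh, 2, 300)
  res <- channelwise_pid(trials_vh, trials_v, trials_h, spec, lambda = 4,
                         folds = 3, seed = 9)
  at <- res$atoms
  # unique-V dominates unique-H on every channel by construction
  expect_gt(mean(at$uniq_v), mean(at$uniq_h) + 0.1)
  expect_gt(mean(at$mi_v), mean(at$mi_h))

  # determinism of the permutation test
  p1 <- permutation_test(res, n_perm = 100, seed = 4)
  p2 <- permutation_test(res, n_perm = 100, seed = 4)
  expect_identical(p1$p, p2$p)
  expect_error(permutation_test(res, n_perm = 50), "100")
})
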
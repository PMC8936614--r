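test_that("simulated trajectories respect the workspace and switching contract", {
  cfg <- sim_config(fs = 100, n_channels = 4)

  # no-switch limit: the finger never leaves its starting side
  cfg0 <- sim_config(fs = 100, switch_rate = 0, n_channels = 4)
  tr0 <- simulate_trajectory(cfg0, duration = 4, seed = 3, start_side = "L")
  expect_true(all(tr0$x < cfg0$midline_x))
  expect_identical(movement_parameters(tr0, cfg0$midline_x, "L")$n_cr, 0L)

  # default config: bounded trace with at least one crossing
  tr <- simulate_trajectory(cfg, duration = 4, seed = 1)
  expect_true(all(tr$x >= 0 & tr$x <= 110))
  expect_true(max(abs(tr$x - 55)) <= 55)
  expect_gte(movement_parameters(tr, 55, "L")$n_cr, 1L)

  # length arithmetic
  tr10 <- simulate_trajectory(cfg, duration = 10, seed = 2)
  expect_length(tr10$x, 1000L)

  # degenerate durations error
  expect_error(simulate_trajectory(cfg, duration = 0.001, seed = 1),
               "degenerate|>= 0.5")
  expect_error(simulate_trajectory(cfg, duration = 0.3, seed = 1), "0.5")
})

test_that("simulated EEG honours the snr contract", {
  cfg <- sim_config(fs = 100, n_channels = 4)
  tr <- simulate_trajectory(cfg, duration = 4, seed = 5)
  v <- compute_velocity(tr)
  attr(v, "fs") <- 100
  pat <- make_forward_pattern(4, 100, seed = 7)

  # snr 0: pure noise, no velocity contribution
  e0 <- simulate_eeg(v, pat, snr = 0, seed = 1)
  expect_lt(max(abs(cor(unclass(e0), v))), 0.2)

  # single nonzero lag, zero noise limit approximated by huge snr:
  # channel is a scaled, shifted copy of the velocity
  lags <- attr(pat, "lags")
  pat1 <- matrix(0, 1, length(lags))
  pat1[1, which(lags == 5)] <- 2.5
  attr(pat1, "lags") <- lags
  e1 <- simulate_eeg(v, pat1, snr = 1e12, seed = 1)
  expect_equal(e1[6:400, 1], 2.5 * v[1:395], tolerance = 1e-5)

  # empirical variance ratio near snr = 1 over a long series
  vlong <- rep(v, 30)
  attr(vlong, "fs") <- 100
  sig <- simulate_eeg(vlong, pat, snr = 1e12, seed = 2)
  noisy <- simulate_eeg(vlong, pat, snr = 1, seed = 2)
  ratio <- apply(sig, 2, var) / apply(noisy - sig, 2, var)
  expect_true(all(abs(ratio - 1) < 0.1))

  expect_error(simulate_eeg(v, pat, snr = -1, seed = 1), "snr")
})

test_that("behaviour simulator matches the closed-form absorption law", {
  # independent oracle: P(upper) = (1 - exp(-2 v a w)) / (1 - exp(-2 v a))
  oracle <- function(v, a, w = 0.5) {
    if (abs(v) < 1e-12) return(w)
    (1 - exp(-2 * v * a * w)) / (1 - exp(-2 * v * a))
  }
  pairs <- list(c(0, 2), c(1, 2), c(0.5, 1.5), c(-1, 1), c(2, 1))
  for (pr in pairs) {
    b <- simulate_behavior(pr[1], pr[2], w = 0.5, seed = 17, n = 20000)
    expect_equal(mean(b$choice == "upper"), oracle(pr[1], pr[2]),
                 tolerance = 0.025)
  }
  # nondecision offset bounds every rt
  b <- simulate_behavior(1, 2, ndt = 2, seed = 3, n = 200)
  expect_true(min(b$rt) > 2)
  expect_error(simulate_behavior(NaN, 2), "finite")
  expect_error(simulate_behavior(1, 2, w = 1.2), "w must")
})

test_that("generate_dataset composes cells, stores truth and is deterministic", {
  cfg <- sim_config(n_participants = 2, n_trials_per_cell = 5,
                    conditions = c("V", "VH"),
                    amplitude_levels = c(0.75, 1.1, 1.5),
                    fs = 50, n_channels = 4, trial_duration = 1,
                    coupling_snr = c(V = 1, H = 1, VH = 2), seed = 9)
  ds1 <- generate_dataset(cfg)
  expect_length(ds1$trials, 2 * 2 * 3 * 5)
  expect_true(all(is.finite(ds1$truth$forward_pattern[["VH"]])))

  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$behavior, ds2$behavior)
  expect_identical(ds1$trials[[7]]$eeg, ds2$trials[[7]]$eeg)

  # gamma1 > 0: drift correlates positively with coupling x s
  beh <- ds1$behavior
  pp <- ds1$truth$participant_params
  drift <- vapply(seq_len(nrow(beh)), function(i) {
    r <- pp[pp$participant == beh$participant[i] &
              pp$condition == beh$condition[i], ]
    r$gamma0 + r$gamma1 * beh$r2[i] * beh$s[i]
  }, numeric(1))
  expect_gt(cor(drift, beh$r2 * beh$s), 0)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(midline_x = 0), "midline")
  expect_error(sim_config(amplitude_levels = c(0.5, 1)), "reference")
  expect_error(sim_config(coupling_snr = c(V = 1, H = 1)), "VH")
  expect_warning(sim_config(coupling_snr = c(V = 2, H = 1, VH = 1)),
                 "VH")
})

test_that("YAML round trip reproduces a config", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_participants = 3, fs = 200,
                        coupling_snr = list(V = 1, H = 0.5, VH = 2),
                        seed = 77), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_participants, 3L)
  expect_equal(cfg$fs, 200)
  expect_equal(cfg$coupling_snr[["H"]], 0.5)
  expect_s3_class(cfg, "sim_config")
})
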
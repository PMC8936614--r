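test_that("compute_velocity differentiates correctly", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  # linear ramp and constant
  expect_equal(compute_velocity(position_trace(10 * t, fs = fs)),
               rep(10, length(t)))
  expect_equal(compute_velocity(position_trace(rep(4, 100), fs = fs)),
               rep(0, 100))
  # analytic derivative of a sine
  v <- compute_velocity(position_trace(sin(2 * pi * t), fs = fs))
  expect_lt(max(abs(v[2:1000] - 2 * pi * cos(2 * pi * t)[2:1000])), 1e-3)
  expect_error(compute_velocity(5, fs = 100), "2 samples|length")
  # first-order consistency with cumulative integration
  vv <- cos(2 * pi * t)
  x <- cumsum(vv) / fs
  expect_lt(max(abs(compute_velocity(x, fs = fs)[10:990] -
                      vv[10:990])), 0.02)
})

test_that("movement parameters count crossings and dwell correctly", {
  fs <- 100
  # constructed trace crossing the midline at 3 distinct times
  x <- c(rep(40, 50), rep(60, 50), rep(40, 50), rep(70, 50))
  mp <- movement_parameters(position_trace(x, fs = fs), midline = 55,
                            low_side = "L")
  expect_identical(mp$n_cr, 3L)
  expect_equal(mp$t_low, 1.0)  # 100 samples left of midline

  # entirely on one side
  x2 <- rep(30, 400)
  mp2 <- movement_parameters(position_trace(x2, fs = fs), midline = 55,
                             low_side = "L")
  expect_identical(mp2$n_cr, 0L)
  expect_equal(mp2$t_low, 4)

  # constant |velocity| = 30 mm/s
  x3 <- 30 * seq(0, 2, by = 1 / fs)
  mp3 <- movement_parameters(position_trace(x3, fs = fs), midline = 200,
                             low_side = "L")
  expect_equal(mp3$v_m, 30)

  # trace on the midline warns
  expect_warning(movement_parameters(position_trace(rep(55, 10), fs = fs),
                                     55, "L"), "midline")

  # samples exactly on the midline carry forward (no double counting)
  x4 <- c(40, 55, 60, 55, 40)
  mp4 <- movement_parameters(position_trace(x4, fs = 1), 55, "L")
  expect_identical(mp4$n_cr, 2L)

  # invariant to y-channel content
  trA <- position_trace(x, y = rnorm(length(x)), fs = fs)
  mpA <- movement_parameters(trA, 55, "L")
  expect_identical(mpA[c("v_m", "n_cr", "t_low")],
                   mp[c("v_m", "n_cr", "t_low")])
})

test_that("qc filter applies the closed RT interval [0.3, 10]", {
  tab <- data.frame(rt = c(0.2, 0.5, 11.0, 4.0))
  res <- qc_filter_trials(tab)
  expect_equal(nrow(res$table), 2L)
  expect_equal(res$fraction_rejected, 0.5)
  expect_identical(res$rejected, c(1L, 3L))

  # identity on in-range tables; exact boundaries kept
  tab2 <- data.frame(rt = c(0.3, 10, 5))
  res2 <- qc_filter_trials(tab2)
  expect_equal(nrow(res2$table), 3L)
  expect_error(qc_filter_trials(data.frame(rt = numeric(0))), "empty")

  # the generator's stated world rejects only a small minority
  beh <- small_dataset()$behavior
  expect_lt(qc_filter_trials(beh)$fraction_rejected, 0.1)
})

test_that("psychometric fit recovers a cumulative Gaussian", {
  diffs <- rep(c(-0.5, -0.25, -0.1, 0.1, 0.25, 0.5), each = 200)
  mk <- function(mu, sigma, seed) {
    withr::with_seed(seed, rbinom(length(diffs), 1,
                                  pnorm((diffs - mu) / sigma)))
  }
  fit <- fit_psychometric(mk(0.05, 0.2, 1), diffs)
  expect_lt(abs(fit$pse - 0.05), 0.03)

  # halving sigma doubles the slope
  f1 <- fit_psychometric(mk(0, 0.3, 2), diffs)
  f2 <- fit_psychometric(mk(0, 0.15, 2), diffs)
  expect_equal(f2$slope / f1$slope, 2, tolerance = 0.3)

  # symmetric proportions give pse ~ 0
  f0 <- fit_psychometric(mk(0, 0.2, 3), diffs)
  expect_lt(abs(f0$pse), 0.03)

  expect_error(fit_psychometric(rep(1, 12), rep(c(-1, 1), 6)),
               "identical")
  expect_error(fit_psychometric(c(0, 1), c(0.1, 0.1)), "distinct")
})
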
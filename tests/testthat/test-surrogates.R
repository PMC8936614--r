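test_that("phase randomisation preserves the amplitude spectrum exactly", {
  set.seed(2)
  for (n in c(64, 101)) {  # even and odd lengths
    x <- rnorm(n)
    s <- phase_randomize(x, seed = 5)
    expect_equal(Mod(fft(s)), Mod(fft(x)), tolerance = 1e-10)
    expect_true(all(abs(Im(fft(s)[1])) < 1e-8))  # output real
    # autocorrelation (periodogram) preserved
    expect_equal(Re(fft(Mod(fft(s))^2, inverse = TRUE)),
                 Re(fft(Mod(fft(x))^2, inverse = TRUE)), tolerance = 1e-6)
  }

  # constant signal: only DC energy, surrogate identical
  const <- rep(3.2, 32)
  expect_equal(phase_randomize(const, seed = 1), const, tolerance = 1e-10)

  # decorrelation: surrogate of y = x is uncorrelated with x on average
  x <- rnorm(1024)
  cors <- vapply(1:200, function(b)
    abs(cor(x, phase_randomize(x, seed = b))), numeric(1))
  expect_lt(mean(cors), 0.05)

  # reproducibility and input validation
  expect_identical(phase_randomize(x, seed = 9), phase_randomize(x, seed = 9))
  expect_error(phase_randomize(c(1, NA, 3, 4)), "finite")
  expect_error(phase_randomize(c(1, 2)), "length")
})

test_that("surrogate null distribution implements the plus-one rule", {
  ds <- small_dataset()
  spec <- small_lag_spec()
  trs <- trials_of(ds, "VH")
  expect_warning(
    sn <- null_r2_distribution(trs, spec, lambda = 4, n = 60, seed = 2,
                               folds = 3),
    "100")
  expect_length(sn$null, 60L)
  expect_gte(sn$p, 1 / 61)
  expect_lte(sn$p, 1)
  # coupled data: observed beats essentially every surrogate
  expect_equal(sn$p, (1 + sum(sn$null >= sn$observed)) / 61)
  expect_lt(sn$p, 0.05)

  # full determinism of the null
  sn2 <- suppressWarnings(
    null_r2_distribution(trs, spec, lambda = 4, n = 60, seed = 2, folds = 3))
  expect_identical(sn$null, sn2$null)

  # re-scoring a fixed decoder is also supported
  sn3 <- suppressWarnings(
    null_r2_distribution(trs, spec, lambda = 4, n = 30, seed = 2,
                         refit = FALSE, folds = 3))
  expect_length(sn3$null, 30L)
})
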
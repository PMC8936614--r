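test_that("lagged design matrix has the documented layout", {
  fs <- 100
  spec0 <- lag_spec(0, 10, fs = fs)   # lags {0, 1}
  e <- matrix(rnorm(60), 30, 2)

  # lags {0} only: design equals the EEG itself
  spec_id <- lag_spec(-4, 4, fs = fs) # quantises to lags {0} at 100 Hz? no:
  expect_equal(lag_spec(-4, 4, fs = 100)$lags, c(0L))
  X <- build_lagged_design(e, lag_spec(-4, 4, fs = 100))
  expect_equal(X, unname(e), ignore_attr = TRUE)

  # 2 channels x 3 lags = 6 columns, channel-major order
  spec3 <- lag_spec(-10, 10, fs = 100)
  X3 <- build_lagged_design(e, spec3)
  expect_equal(ncol(X3), 6L)

  # +10 ms lag at 100 Hz shifts by exactly one sample: column[t] = m(t+1)
  d <- numeric(30); d[10] <- 1
  Xd <- build_lagged_design(cbind(d), spec3)
  expect_equal(which(Xd[, 3] == 1), 9L)   # lag +1 column
  expect_equal(which(Xd[, 1] == 1), 11L)  # lag -1 column

  expect_error(build_lagged_design(e[1:2, ], spec3), "shorter")
})

test_that("ridge at lambda 0 equals the normal-equation oracle", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(10:50, 1)
    p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_ridge(X, y, lambda = 0)
    # brute-force oracle in the same standardised space
    Xs <- scale(X); ys <- scale(y)
    w_or <- solve(crossprod(Xs), crossprod(Xs, drop(ys)))
    expect_lt(max(abs(fit$w - drop(w_or))), 1e-8)
  }
})

test_that("ridge limits and invariances hold", {
  set.seed(4)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(1, -2, 0.5, 0))

  # exact linear combination at lambda 0: training r2 = 1
  fit <- fit_ridge(X, y, 0)
  expect_equal(cor(predict_ridge(fit, X), y)^2, 1, tolerance = 1e-10)

  # shrinkage limit
  fit_big <- fit_ridge(X, y, 1e9)
  expect_lt(max(abs(fit_big$w)), 1e-4)

  # collinear design at lambda 0 errors with advice
  Xc <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_ridge(Xc, y, 0), "lambda > 0")
})

test_that("single-trial scoring behaves at the coupling limits", {
  ds <- small_dataset()
  spec <- small_lag_spec()
  trs <- trials_of(ds, "VH")

  sc <- score_single_trials(trs, spec, lambda = 4, folds = 3, seed = 1)
  expect_true(all(sc$r2 >= 0 & sc$r2 <= 1))

  # doubling all channels leaves r2 unchanged (correlation scale invariance)
  trs2 <- lapply(trs, function(tr) { tr$eeg <- tr$eeg * 2; tr })
  sc2 <- score_single_trials(trs2, spec, lambda = 4, folds = 3, seed = 1)
  expect_equal(sc2$r2, sc$r2, tolerance = 1e-8)

  # EEG independent of velocity scores near zero
  trs0 <- lapply(trs, function(tr) {
    tr$eeg <- matrix(rnorm(length(tr$eeg)), nrow(tr$eeg))
    tr
  })
  sc0 <- score_single_trials(trs0, spec, lambda = 4, folds = 3, seed = 1)
  expect_lt(mean(sc0$r2), 0.1)
  expect_gt(mean(sc$r2), mean(sc0$r2))
})

test_that("lambda selection reports the CV curve and degenerate folds", {
  ds <- small_dataset()
  spec <- small_lag_spec()
  trs <- trials_of(ds, "VH")
  expect_error(select_lambda_cv(trs, spec, grid = numeric(0)), "empty")

  # single trial duplicated in all folds: identical per-fold scores
  dup <- rep(trs[1], 6)
  cv <- select_lambda_cv(dup, spec, grid = c(1, 4), folds = 3, seed = 1)
  expect_s3_class(cv$curve, "data.frame")

  # pure-noise target: flat near-zero curve warns
  noise <- lapply(trs, function(tr) {
    tr$velocity <- rnorm(length(tr$velocity)); tr
  })
  expect_warning(select_lambda_cv(noise, spec, grid = 2^(0:4), seed = 1),
                 "flat|unrelated")
})

test_that("forward-model inversion recovers interpretable patterns", {
  ds <- small_dataset()
  spec <- small_lag_spec()
  trs <- trials_of(ds, "VH")
  dec <- fit_decoder(trs, spec, lambda = 4)
  fwd <- to_forward_model(dec, trs)
  expect_equal(dim(unclass(fwd)), dim(dec$g))
  expect_true(all(is.finite(fwd)))

  # scaling the EEG leaves the pattern shape invariant (up to overall scale)
  trsc <- lapply(trs, function(tr) { tr$eeg <- tr$eeg * 3; tr })
  decc <- fit_decoder(trsc, spec, lambda = 4)
  fwdc <- to_forward_model(decc, trsc)
  expect_gt(abs(cor(as.vector(unclass(fwd)), as.vector(unclass(fwdc)))),
            0.999)

  # whitened data: pattern proportional to the weights
  set.seed(8)
  n <- 500
  W <- matrix(rnorm(n * 3), n, 3)  # ~ white channels
  y <- drop(W %*% c(1, -0.5, 0.2)) + rnorm(n, sd = 0.1)
  tr_white <- list(list(eeg = W, velocity = y))
  spec0 <- lag_spec(-4, 4, fs = 100)  # single lag 0
  decw <- fit_decoder(tr_white, spec0, lambda = 0.01)
  fww <- to_forward_model(decw, tr_white)
  gn <- decw$w * decw$y_sd / decw$col_sds
  expect_gt(abs(cor(as.vector(unclass(fww)), gn)), 0.999)
})

test_that("encoding models predict channels from lagged velocity", {
  ds <- small_dataset()
  spec <- small_lag_spec()
  trs <- trials_of(ds, "VH")
  enc <- fit_encoding(trs, spec, lambda = 4)
  pred <- predict_encoding(enc, trs[[1]]$velocity)
  expect_equal(dim(pred), dim(unclass(trs[[1]]$eeg)))
  # predictions correlate with the measured channels (coupled condition)
  cors <- vapply(seq_len(ncol(pred)), function(ch)
    cor(pred[, ch], trs[[1]]$eeg[, ch]), numeric(1))
  expect_gt(mean(abs(cors)), 0.2)
})
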
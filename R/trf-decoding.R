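#' Lag specification for temporal response functions
#'
#' Time lags, in ms, over which EEG channels inform instantaneous finger
#' velocity; the default window spans -200 ms (EEG preceding velocity) to
#' +400 ms (EEG following it), quantised to the sample period.
#'
#' @param lag_min,lag_max Lag range, ms.
#' @param fs Sampling rate, Hz.
#' @return A `lag_spec` list with `lags` in samples.
#' @export
lag_spec <- function(lag_min = -200, lag_max = 400, fs) {
  if (lag_min >= lag_max) stop("lag_min must be < lag_max")
  lags <- seq(round(lag_min * fs / 1000), round(lag_max * fs / 1000))
  structure(list(lag_min = lag_min, lag_max = lag_max, fs = fs, lags = lags),
            class = "lag_spec")
}

#' Build the time-lagged EEG design matrix
#'
#' Row `t` holds `m(t + tau, i)` for every channel `i` and lag `tau`;
#' samples falling outside the trial are zero-padded. Column order is
#' channel-major, lag-minor (all lags of channel 1, then channel 2, ...),
#' fixed and relied upon by the decoder and forward-model code.
#'
#' @param eeg Matrix, time x channels.
#' @param spec A [lag_spec()].
#' @return Matrix, time x (channels * lags).
#' @export
build_lagged_design <- function(eeg, spec) {
  eeg <- as.matrix(eeg)
  n <- nrow(eeg)
  if (n <= length(spec$lags))
    stop("trial shorter than the lag span")
  nch <- ncol(eeg)
  out <- matrix(0, n, nch * length(spec$lags))
  col <- 0L
  for (i in seq_len(nch)) {
    for (tau in spec$lags) {
      col <- col + 1L
      # column[t] = m(t + tau, i)
      out[, col] <- shift_series(eeg[, i], -tau)
    }
  }
  out
}

#' Ridge regression with internal standardisation
#'
#' Solves `w = (X'X + lambda I)^-1 X'y` in the z-scored space (identity
#' penalty on the standardised Gram diagonal; the intercept is implicit and
#' unpenalised), keeping the standardisation so predictions come back in
#' native units.
#'
#' @param design Design matrix.
#' @param target Target vector.
#' @param lambda Ridge penalty, >= 0.
#' @return A `ridge_fit` list with standardised weights and scaling info.
#' @export
fit_ridge <- function(design, target, lambda) {
  if (nrow(design) != length(target))
    stop("rows(design) must equal length(target)")
  if (lambda < 0) stop("lambda must be >= 0")
  mx <- colMeans(design)
  sx <- apply(design, 2, sd)
  sx[sx == 0] <- 1
  Xs <- sweep(sweep(design, 2, mx), 2, sx, "/")
  my <- mean(target)
  sy <- sd(target)
  if (sy == 0) sy <- 1
  ys <- (target - my) / sy
  G <- crossprod(Xs)
  diag(G) <- diag(G) + lambda
  w <- tryCatch(solve(G, crossprod(Xs, ys)),
                error = function(e)
                  stop("singular system; use lambda > 0 for collinear designs",
                       call. = FALSE))
  structure(list(w = drop(w), lambda = lambda, col_means = mx, col_sds = sx,
                 y_mean = my, y_sd = sy), class = "ridge_fit")
}

#' @rdname fit_ridge
#' @param fit A `ridge_fit`.
#' @param design New design matrix.
#' @export
predict_ridge <- function(fit, design) {
  Xs <- sweep(sweep(design, 2, fit$col_means), 2, fit$col_sds, "/")
  drop(Xs %*% fit$w) * fit$y_sd + fit$y_mean
}

concat_trials <- function(trials, spec) {
  Xs <- lapply(trials, function(tr) build_lagged_design(tr$eeg, spec))
  list(X = do.call(rbind, Xs), y = unlist(lapply(trials, `[[`, "velocity")))
}

#' Fit a velocity decoder on a set of trials
#'
#' Trains one ridge decoder on the concatenation of the given trials
#' (one filter per participant x condition is the intended granularity).
#'
#' @param trials List of trials, each with `eeg` (time x channels) and
#'   `velocity`.
#' @param spec A [lag_spec()].
#' @param lambda Ridge penalty; the pipeline default is `2^2`, the value
#'   that cross-validation identifies as lying on the flat part of the
#'   accuracy curve.
#' @return A `decoder_model`: the `ridge_fit` plus the weights reshaped to
#'   channels x lags (`g`), lag spec and channel labels.
#' @export
fit_decoder <- function(trials, spec, lambda = 4) {
  dat <- concat_trials(trials, spec)
  fit <- fit_ridge(dat$X, dat$y, lambda)
  nl <- length(spec$lags)
  nch <- ncol(as.matrix(trials[[1]]$eeg))
  g <- matrix(fit$w, nrow = nch, ncol = nl, byrow = TRUE)
  labels <- attr(trials[[1]]$eeg, "labels") %||% paste0("ch", seq_len(nch))
  structure(c(fit, list(g = g, lag_spec = spec, labels = labels)),
            class = c("decoder_model", "ridge_fit"))
}

#' Cross-validated ridge-parameter selection
#'
#' Splits the training trials into `folds` folds by trial, fits the decoder
#' at every penalty in `grid` and returns the penalty maximising the mean
#' held-out squared correlation, along with the full CV curve. On
#' well-coupled data the curve is typically flat across the low end of the
#' grid, which is why the pipeline fixes `lambda = 2^2` by default and uses
#' this function diagnostically.
#'
#' @param trials List of trials (>= `folds`).
#' @param spec A [lag_spec()].
#' @param grid Candidate penalties (default `2^(0:20)`).
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return List with `lambda`, `curve` (data frame lambda/mean r2), and
#'   `flat` (logical: top of curve within 5% across `2^0..2^4`).
#' @export
select_lambda_cv <- function(trials, spec, grid = 2^(0:20), folds = 5,
                             seed = 1L) {
  if (!length(grid)) stop("lambda grid is empty")
  if (length(trials) < folds)
    stop("need at least as many trials as folds")
  fold_of <- with_seed(seed,
    sample(rep_len(seq_len(folds), length(trials))))
  scores <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- trials[fold_of != f]
    te <- trials[fold_of == f]
    dat <- concat_trials(tr, spec)
    mx <- colMeans(dat$X); sx <- apply(dat$X, 2, sd); sx[sx == 0] <- 1
    Xs <- sweep(sweep(dat$X, 2, mx), 2, sx, "/")
    my <- mean(dat$y); sy <- sd(dat$y); if (sy == 0) sy <- 1
    ys <- (dat$y - my) / sy
    eg <- eigen(crossprod(Xs), symmetric = TRUE)
    Xty <- crossprod(Xs, ys)
    Vt_Xty <- crossprod(eg$vectors, Xty)
    for (g in seq_along(grid)) {
      w <- eg$vectors %*% (Vt_Xty / (eg$values + grid[g]))
      r2s <- vapply(te, function(trl) {
        Xte <- build_lagged_design(trl$eeg, spec)
        Xte <- sweep(sweep(Xte, 2, mx), 2, sx, "/")
        pred <- drop(Xte %*% w)
        if (sd(pred) == 0) return(0)
        cor(pred, trl$velocity)^2
      }, numeric(1))
      scores[f, g] <- mean(r2s)
    }
  }
  curve <- data.frame(lambda = grid, r2 = colMeans(scores))
  best <- which.max(curve$r2)
  low <- curve$r2[curve$lambda >= 1 & curve$lambda <= 16]
  flat <- length(low) > 1 &&
    (max(low) - min(low)) <= 0.05 * max(max(low), .Machine$double.eps)
  if (max(curve$r2) < 0.01)
    warning("flat near-zero CV curve: target appears unrelated to EEG")
  list(lambda = curve$lambda[best], curve = curve, flat = flat)
}

#' Single-trial reconstruction accuracy by cross-fitting
#'
#' Five-fold cross-fitting over trials: each trial's velocity is
#' reconstructed by a decoder trained only on the other folds, and scored
#' by the squared Pearson correlation between measured and reconstructed
#' velocity. An 80/20 single-split mode (`mode = "holdout"`) is also
#' exposed; it scores only the held-out 20% of trials.
#'
#' @param trials List of trials.
#' @param spec A [lag_spec()].
#' @param lambda Ridge penalty.
#' @param folds Number of folds.
#' @param seed Seed for fold assignment.
#' @param mode `"crossfit"` (default) or `"holdout"`.
#' @param train_frac Training fraction for holdout mode.
#' @return Data frame with `trial`, `r2`, `fold`; rows are `NA` for trials
#'   shorter than the lag span (flagged, not dropped).
#' @export
score_single_trials <- function(trials, spec, lambda = 4, folds = 5,
                                seed = 1L, mode = c("crossfit", "holdout"),
                                train_frac = 0.8) {
  mode <- match.arg(mode)
  nt <- length(trials)
  ok <- vapply(trials, function(tr) nrow(as.matrix(tr$eeg)) > length(spec$lags),
               logical(1))
  r2 <- rep(NA_real_, nt)
  if (mode == "holdout") {
    idx <- with_seed(seed, sample(which(ok)))
    ntr <- max(1L, round(train_frac * length(idx)))
    train <- idx[seq_len(ntr)]
    test <- setdiff(idx, train)
    dec <- fit_decoder(trials[train], spec, lambda)
    for (i in test) r2[i] <- trial_r2(dec, trials[[i]], spec)
    return(data.frame(trial = seq_len(nt), r2 = r2,
                      fold = ifelse(seq_len(nt) %in% test, 1L, NA_integer_)))
  }
  fold_of <- rep(NA_integer_, nt)
  fold_of[ok] <- with_seed(seed, sample(rep_len(seq_len(folds), sum(ok))))
  for (f in seq_len(folds)) {
    train <- which(fold_of != f & ok)
    test <- which(fold_of == f)
    if (!length(train) || !length(test)) next
    dec <- fit_decoder(trials[train], spec, lambda)
    for (i in test) r2[i] <- trial_r2(dec, trials[[i]], spec)
  }
  data.frame(trial = seq_len(nt), r2 = r2, fold = fold_of)
}

trial_r2 <- function(decoder, trial, spec) {
  X <- build_lagged_design(trial$eeg, spec)
  pred <- predict_ridge(decoder, X)
  if (sd(pred) == 0 || sd(trial$velocity) == 0) return(0)
  cor(pred, trial$velocity)^2
}

#' Invert a decoder into an interpretable forward model
#'
#' Transforms decoding weights `g` into an encoding pattern
#' `f = (M'M) g / (s_hat' s_hat)` where `M` is the (standardised) lagged
#' EEG design the decoder was trained with and `s_hat = M g` the
#' reconstructed velocity: the covariance-transformed pattern that is
#' interpretable in terms of neural sources, unlike the raw decoder
#' weights.
#'
#' @param decoder A `decoder_model`.
#' @param trials The trials defining the data covariance (typically the
#'   training trials).
#' @return A `forward_model`: matrix channels x lags with attribute `lags`.
#' @export
to_forward_model <- function(decoder, trials) {
  spec <- decoder$lag_spec
  dat <- concat_trials(trials, spec)
  Xc <- sweep(dat$X, 2, colMeans(dat$X))
  # decoder weights back in native units (the standardisation is internal
  # to the ridge solve; the pattern lives in measured-EEG space)
  g_native <- decoder$w * decoder$y_sd / decoder$col_sds
  shat <- drop(Xc %*% g_native)
  denom <- sum(shat^2)
  if (denom == 0) stop("zero-variance reconstruction: cannot invert decoder")
  f <- drop(crossprod(Xc, shat)) / denom
  fm <- matrix(f, nrow = nrow(decoder$g), ncol = ncol(decoder$g),
               byrow = TRUE)
  structure(fm, lags = spec$lags, labels = decoder$labels,
            class = "forward_model")
}

#' Fit per-channel velocity-encoding models
#'
#' The encoding (forward) direction used by the information decomposition:
#' each EEG channel is predicted from lagged finger velocity by ridge
#' regression (one shared lagged-velocity design, multi-target solve).
#'
#' @param trials List of trials with `eeg` and `velocity`.
#' @param spec A [lag_spec()].
#' @param lambda Ridge penalty.
#' @return An `encoder_model` with weights `W` (lags x channels) and
#'   standardisation info.
#' @export
fit_encoding <- function(trials, spec, lambda = 4) {
  X <- do.call(rbind, lapply(trials, function(tr)
    lagged_velocity_design(tr$velocity, spec)))
  Y <- do.call(rbind, lapply(trials, function(tr) as.matrix(tr$eeg)))
  mx <- colMeans(X); sx <- apply(X, 2, sd); sx[sx == 0] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- colMeans(Y)
  Yc <- sweep(Y, 2, my)
  G <- crossprod(Xs)
  diag(G) <- diag(G) + lambda
  W <- solve(G, crossprod(Xs, Yc))
  structure(list(W = W, col_means = mx, col_sds = sx, y_means = my,
                 lag_spec = spec, lambda = lambda,
                 labels = attr(trials[[1]]$eeg, "labels")),
            class = "encoder_model")
}

#' @rdname fit_encoding
#' @param model An `encoder_model`.
#' @param velocity Velocity series of one trial.
#' @return Predicted channel activity, time x channels.
#' @export
predict_encoding <- function(model, velocity) {
  X <- lagged_velocity_design(velocity, model$lag_spec)
  Xs <- sweep(sweep(X, 2, model$col_means), 2, model$col_sds, "/")
  sweep(Xs %*% model$W, 2, model$y_means, "+")
}

# design for the encoding direction: column j holds v(t - tau_j), the same
# lag axis as the decoder (EEG at t reflects velocity tau earlier)
lagged_velocity_design <- function(velocity, spec) {
  out <- matrix(0, length(velocity), length(spec$lags))
  for (j in seq_along(spec$lags))
    out[, j] <- shift_series(as.numeric(velocity), spec$lags[j])
  out
}
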
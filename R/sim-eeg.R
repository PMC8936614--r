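#' Ground-truth velocity-encoding pattern
#'
#' Builds the channels x lags mixing kernel used by the EEG generator: each
#' channel responds to finger velocity through a smooth (Gaussian-bump) lag
#' kernel whose peak lies in the 20-160 ms range where velocity encoding is
#' expected, with channel-specific random amplitude and sign. Lags span
#' `lag_ms` on the sampling grid `fs`.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate, Hz.
#' @param lag_ms Lag range of the kernel, ms (within \[-200, 400\]).
#' @param seed Integer seed.
#' @return Matrix (channels x lags) with attributes `lags` (sample offsets)
#'   and `labels`.
#' @export
make_forward_pattern <- function(n_channels, fs, lag_ms = c(-200, 400),
                                 seed = 1L) {
  if (lag_ms[1] < -200 || lag_ms[2] > 400)
    stop("pattern lags must lie within [-200, 400] ms")
  lags <- seq(round(lag_ms[1] * fs / 1000), round(lag_ms[2] * fs / 1000))
  lag_t <- lags / fs * 1000  # ms
  with_seed(seed, {
    centers <- runif(n_channels, 20, 160)
    # kernel widths comparable to the velocity autocorrelation width: the
    # regime in which covariance-based (encoding) patterns are identifiable
    widths <- runif(n_channels, 80, 120)
    amps <- rnorm(n_channels) * sample(c(1, 1, 1, -1), n_channels,
                                       replace = TRUE)
    f <- vapply(seq_len(n_channels), function(i) {
      amps[i] * exp(-(lag_t - centers[i])^2 / (2 * widths[i]^2))
    }, numeric(length(lags)))
    f <- t(f)  # channels x lags
    structure(f, lags = lags,
              labels = montage_1010()[seq_len(n_channels)])
  })
}

#' Simulate multichannel EEG coupled to finger velocity
#'
#' Each channel is the lagged convolution of the velocity series with that
#' channel's kernel from `pattern`, plus white Gaussian noise scaled so that
#' the channel-wise ratio of signal variance to noise variance equals `snr`.
#' With `snr = 0` the velocity contribution is dropped entirely and the
#' channels are pure unit-variance noise.
#'
#' @param velocity Velocity series, mm/s.
#' @param pattern Kernel from [make_forward_pattern()] (channels x lags,
#'   with a `lags` attribute in samples).
#' @param snr Signal-to-noise variance ratio, >= 0.
#' @param seed Integer seed.
#' @return An `eeg_trace`: matrix (time x channels) with attributes `fs`
#'   (taken from `attr(velocity, "fs")` when present) and `labels`.
#' @export
simulate_eeg <- function(velocity, pattern, snr, seed = 1L) {
  if (snr < 0) stop("snr must be >= 0")
  lags <- attr(pattern, "lags")
  if (is.null(lags)) stop("pattern must carry a 'lags' attribute")
  n <- length(velocity)
  nch <- nrow(pattern)
  sig <- matrix(0, n, nch)
  if (snr > 0) {
    for (j in seq_along(lags)) {
      v_shift <- shift_series(velocity, lags[j])
      sig <- sig + tcrossprod(v_shift, pattern[, j])
    }
  }
  with_seed(seed, {
    out <- matrix(0, n, nch)
    for (i in seq_len(nch)) {
      s_var <- var(sig[, i])
      noise_sd <- if (snr > 0 && s_var > 0) sqrt(s_var / snr) else 1
      out[, i] <- sig[, i] + rnorm(n, sd = noise_sd)
    }
    structure(out, fs = attr(velocity, "fs"),
              labels = attr(pattern, "labels"), class = "eeg_trace")
  })
}

# shift x by k samples: result[t] = x[t - k], zero-padded.
# With m(t) responding to v(t - lag), the decoder reading m(t + lag)
# recovers v(t), so generator and decoder share one lag axis.
shift_series <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  if (k >= 0) {
    if (k < n) out[(k + 1):n] <- x[1:(n - k)]
  } else {
    if (-k < n) out[1:(n + k)] <- x[(1 - k):n]
  }
  out
}
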
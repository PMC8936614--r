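#' Phase-randomisation surrogate of a time series
#'
#' Returns a series with the original's amplitude spectrum bin-by-bin but
#' i.i.d. uniform phases at the positive frequencies (DC and Nyquist bins
#' untouched, conjugate symmetry enforced), so the surrogate is real,
#' shares the original's periodogram — hence its autocorrelation — but has
#' no temporal relation to any other signal.
#'
#' @param signal Real finite series, length >= 4.
#' @param seed Integer seed.
#' @return Surrogate series, same length.
#' @export
phase_randomize <- function(signal, seed = 1L) {
  x <- as.numeric(signal)
  if (!all(is.finite(x))) stop("signal must be finite")
  n <- length(x)
  if (n < 4L) stop("signal must have length >= 4")
  F <- fft(x)
  half <- floor(n / 2)
  # positive-frequency bins excluding DC (index 1) and, for even n, Nyquist
  pos <- 2:(if (n %% 2 == 0) half else half + 1)
  if (n %% 2 == 0) pos <- 2:half
  phases <- with_seed(seed, runif(length(pos), 0, 2 * pi))
  F[pos] <- Mod(F[pos]) * exp(1i * phases)
  F[n + 2 - pos] <- Conj(F[pos])
  Re(fft(F, inverse = TRUE)) / n
}

#' Surrogate null distribution for decoding accuracy
#'
#' Repeats the decode-and-score analysis on `n` phase-randomised copies of
#' the EEG (every channel of every trial randomised with an independent
#' seeded phase draw; optionally a shared draw per trial preserving
#' cross-spectra), yielding an empirical null for the mean reconstruction
#' accuracy and a plus-one permutation p-value
#' `p = (1 + #{null >= observed}) / (1 + n)`.
#'
#' By default decoders are re-fitted on each surrogate (the stricter test);
#' `refit = FALSE` re-scores the fixed observed decoder instead.
#'
#' @param trials List of trials.
#' @param spec A [lag_spec()].
#' @param lambda Ridge penalty.
#' @param n Number of surrogates (>= 100 for stable tails; fewer triggers a
#'   warning).
#' @param seed Integer seed.
#' @param refit Refit the decoder per surrogate?
#' @param shared_phase Use one phase draw per trial across channels?
#' @param folds Cross-fitting folds for scoring.
#' @return A `surrogate_null` list: `observed`, `null` (length `n`), `p`,
#'   `n_surrogates`.
#' @export
null_r2_distribution <- function(trials, spec, lambda = 4, n = 1000,
                                 seed = 1L, refit = TRUE,
                                 shared_phase = FALSE, folds = 5) {
  if (n < 100)
    warning("fewer than 100 surrogates: tail estimates will be unstable")
  obs <- mean(score_single_trials(trials, spec, lambda, folds = folds,
                                  seed = derive_seed(seed, "score"))$r2,
              na.rm = TRUE)
  dec_fixed <- if (!refit) fit_decoder(trials, spec, lambda)
  null <- numeric(n)
  for (b in seq_len(n)) {
    surr <- lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      eeg <- as.matrix(tr$eeg)
      for (ch in seq_len(ncol(eeg))) {
        s <- if (shared_phase) derive_seed(seed, "ph", b, i)
             else derive_seed(seed, "ph", b, i, ch)
        eeg[, ch] <- phase_randomize(eeg[, ch], seed = s)
      }
      tr$eeg <- eeg
      tr
    })
    null[b] <- if (refit) {
      mean(score_single_trials(surr, spec, lambda, folds = folds,
                               seed = derive_seed(seed, "score"))$r2,
           na.rm = TRUE)
    } else {
      mean(vapply(surr, function(tr) trial_r2(dec_fixed, tr, spec),
                  numeric(1)))
    }
  }
  p <- (1 + sum(null >= obs)) / (1 + n)
  structure(list(observed = obs, null = null, p = p, n_surrogates = n),
            class = "surrogate_null")
}
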
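#' @useDynLib actsense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor cov convolve dnorm fft glm optimize
#'   pnorm qnorm quantile rbeta rbinom rexp rnorm runif sd var setNames
#'   binomial p.adjust mvfft
#' @importFrom utils read.csv write.csv head tail
NULL

# Deterministic substream derivation: mixes a parent seed with an arbitrary
# sequence of integer/string keys into a new seed < 2^31 (R integers are
# 32-bit). Used so that every stage / participant / trial gets an
# independent, reproducible stream from one global seed.
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    for (ki in as.double(k)) {
      h <- (h * 48271 + ki + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483629 + 1)
}

# run expr with a local RNG state seeded by `seed`; restores caller state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
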
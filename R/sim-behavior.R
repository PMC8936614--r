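#' Simulate choices and response times from a drift-diffusion process
#'
#' Euler-Maruyama simulation of a Wiener accumulator with unit diffusion
#' coefficient: evidence starts at `w * boundary` and evolves with drift
#' until absorption at 0 (lower boundary, here an error) or `boundary`
#' (upper boundary, a correct response). The response time is the
#' first-passage time plus the nondecision time `ndt`.
#'
#' @param drift Drift rate, evidence/s.
#' @param boundary Boundary separation, > 0.
#' @param ndt Nondecision time, s.
#' @param w Starting-point fraction in (0, 1).
#' @param seed Integer seed.
#' @param n Number of independent paths.
#' @param dt Euler step, s (<= 1e-3 recommended; default 0.5 ms).
#' @param tmax Censoring horizon for the decision time, s.
#' @return Data frame with columns `choice` (`"upper"`/`"lower"`, `NA` if
#'   censored) and `rt` (s).
#' @export
simulate_behavior <- function(drift, boundary, ndt = 0, w = 0.5, seed = 1L,
                              n = 1L, dt = 5e-4, tmax = 60) {
  if (!is.finite(drift)) stop("drift must be finite")
  stopifnot_scalar(boundary, "boundary", positive = TRUE)
  if (w <= 0 || w >= 1) stop("w must lie strictly in (0, 1)")
  res <- with_seed(seed, .ddm_sim_cpp(as.integer(n), drift, boundary, w, dt,
                                      tmax))
  choice <- ifelse(is.na(res[, 1]), NA_character_,
                   ifelse(res[, 1] == 1, "upper", "lower"))
  data.frame(choice = choice, rt = res[, 2] + ndt)
}

#' Closed-form upper-boundary absorption probability
#'
#' For a unit-noise Wiener process with drift `v`, boundary separation `a`
#' and starting fraction `w`, the probability of absorption at the upper
#' boundary is `(1 - exp(-2 v a w)) / (1 - exp(-2 v a))` (and `w` when
#' `v = 0`). Used as the independent oracle for the stochastic simulator
#' and the first-passage density.
#'
#' @param drift,boundary,w Process parameters.
#' @return Probability of upper-boundary absorption.
#' @export
absorption_prob_upper <- function(drift, boundary, w = 0.5) {
  if (abs(drift) < 1e-12) return(w)
  (1 - exp(-2 * drift * boundary * w)) / (1 - exp(-2 * drift * boundary))
}
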
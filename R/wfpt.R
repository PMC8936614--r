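#' Wiener first-passage-time log density
#'
#' Log density of the decision time `t` for a unit-noise Wiener diffusion
#' with drift `drift`, boundary separation `boundary` and starting fraction
#' `w`, absorbed at the lower boundary (default) or the upper boundary
#' (obtained by the reflection `(drift, w) -> (-drift, 1 - w)`). The
#' normalized-time density is evaluated by whichever of the small-time and
#' large-time series expansions needs fewer terms for truncation error
#' `<= eps`, then rescaled by
#' `f(t | v, a, w) = a^-2 exp(-v a w - v^2 t / 2) f(t / a^2 | 0, 1, w)`.
#'
#' @param t Decision time(s), s; non-positive values give `-Inf`.
#' @param drift Drift rate.
#' @param boundary Boundary separation, > 0.
#' @param w Starting-point fraction in (0, 1).
#' @param upper Density of upper-boundary absorption instead of lower?
#' @param eps Series truncation tolerance, in (0, 1e-4].
#' @return Log density, vectorised over `t` (parameters recycled).
#' @export
wfpt_logpdf <- function(t, drift, boundary, w = 0.5, upper = FALSE,
                        eps = 1e-6) {
  if (eps <= 0 || eps > 1e-4) stop("eps must lie in (0, 1e-4]")
  if (any(boundary <= 0)) stop("boundary must be > 0")
  if (any(w <= 0 | w >= 1)) stop("w must lie in (0, 1)")
  .wfpt_logpdf_cpp(as.numeric(t), as.numeric(drift), as.numeric(boundary),
                   as.numeric(w), as.logical(upper), eps)
}

#' Log likelihood of one behavioural trial under the DDM
#'
#' Accuracy coding: the upper boundary is the correct response. The density
#' is evaluated at the decision time `rt - ndt`; trials with `rt <= ndt`
#' return `-Inf` (an impossible datum, not an exception, so samplers can
#' reject the proposal).
#'
#' @param rt Response time, s.
#' @param accuracy 1 = correct (upper boundary), 0 = error (lower).
#' @param drift,boundary,ndt,w DDM parameters.
#' @param eps Series tolerance.
#' @return Log likelihood (vectorised; parameters recycled).
#' @export
trial_loglik <- function(rt, accuracy, drift, boundary, ndt, w = 0.5,
                         eps = 1e-6) {
  n <- max(length(rt), length(accuracy), length(drift), length(boundary),
           length(ndt))
  rt <- rep_len(rt, n); accuracy <- rep_len(accuracy, n)
  drift <- rep_len(drift, n); boundary <- rep_len(boundary, n)
  ndt <- rep_len(ndt, n)
  t <- rt - ndt
  out <- rep(-Inf, n)
  pos <- t > 0 & boundary > 0 & ndt >= 0
  if (any(pos)) {
    out[pos] <- .wfpt_logpdf_cpp(t[pos], drift[pos], boundary[pos],
                                 rep_len(w, sum(pos)),
                                 accuracy[pos] == 1, eps)
  }
  out
}
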
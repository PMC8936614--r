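#' Simulate a finger-scanning trajectory
#'
#' Generates a 1-D finger-position trace emulating free left/right scanning
#' of a split workspace. The model is a smoothed telegraph process: the
#' finger's "home side" switches between the two subspaces at exponential
#' dwell times (mean rate `cfg$switch_rate`), and a bounded oscillation
#' (frequency `cfg$scan_freq`, amplitude `cfg$scan_amp`) emulates the
#' within-side scanning of the texture. Two features keep the velocity
#' spectrum realistic rather than a pure line: the oscillation's
#' instantaneous frequency and amplitude drift slowly (smoothed
#' multiplicative jitter), and a broadband corrective-submovement component
#' (`cfg$jitter_amp` mm, correlation time `cfg$jitter_tc` s) is added,
#' emulating the small corrections and tremor present in real finger
#' movement. Without the broadband component the velocity autocorrelation
#' never decays and covariance-based encoding patterns are unidentifiable.
#' The side-step component is smoothed with a Gaussian kernel (sd 120 ms)
#' so the trace is differentiable, then the sum is clamped to the
#' workspace.
#'
#' @param cfg A [sim_config()].
#' @param duration Trial length in seconds (>= 0.5).
#' @param seed Integer seed.
#' @param start_side Optional starting side, `"L"` or `"R"`; chosen at
#'   random when `NULL`.
#' @return A `position_trace` list with fields `x` (mm), `fs`, `t0`.
#' @export
simulate_trajectory <- function(cfg, duration = cfg$trial_duration, seed = 1L,
                                start_side = NULL) {
  stopifnot_scalar(duration, "duration")
  if (duration < 1 / cfg$fs)
    stop("degenerate trial: duration shorter than one sample period")
  if (duration < 0.5)
    stop("duration must be >= 0.5 s")
  n <- round(duration * cfg$fs)
  dt <- 1 / cfg$fs
  half <- (cfg$midline_x - cfg$workspace_x[1])
  centers <- c(L = cfg$workspace_x[1] + half / 2,
               R = cfg$midline_x + (cfg$workspace_x[2] - cfg$midline_x) / 2)
  with_seed(seed, {
    side <- start_side %||% sample(c("L", "R"), 1L)
    # telegraph process: piecewise-constant home side
    step <- numeric(n)
    i <- 1L
    while (i <= n) {
      dwell <- if (cfg$switch_rate > 0) rexp(1, cfg$switch_rate) else Inf
      j <- min(n, i + max(1L, round(dwell * cfg$fs)) - 1L)
      step[i:j] <- centers[[side]]
      side <- if (side == "L") "R" else "L"
      i <- j + 1L
    }
    phase0 <- runif(1, 0, 2 * pi)
    # slow multiplicative drift of scan frequency and amplitude
    fdrift <- 1 + 0.35 * gaussian_smooth(rnorm(n), sd_s = 0.3, fs = cfg$fs) /
      smooth_sd_norm(0.3, cfg$fs)
    adrift <- 1 + 0.25 * gaussian_smooth(rnorm(n), sd_s = 0.3, fs = cfg$fs) /
      smooth_sd_norm(0.3, cfg$fs)
    phase <- phase0 + cumsum(2 * pi * cfg$scan_freq * pmax(fdrift, 0.2) * dt)
    osc <- cfg$scan_amp * pmin(pmax(adrift, 0.5), 1.25) * sin(phase)
    # broadband corrective submovements / tremor
    jit_tc <- cfg$jitter_tc %||% 0.025
    jit_amp <- cfg$jitter_amp %||% 4
    jit <- gaussian_smooth(rnorm(n), sd_s = jit_tc, fs = cfg$fs)
    sdj <- sd(jit)
    if (sdj > 0) jit <- jit / sdj * jit_amp else jit <- jit * 0
    # soft-clamp the within-side excursion so the finger stays on its home
    # side unless the telegraph process switches (midline crossings are
    # then governed by switch_rate alone)
    lim <- 0.95 * min(cfg$midline_x - centers[["L"]],
                      centers[["L"]] - cfg$workspace_x[1],
                      centers[["R"]] - cfg$midline_x,
                      cfg$workspace_x[2] - centers[["R"]])
    dev <- osc + jit
    dev <- lim * tanh(dev / lim)
    x <- gaussian_smooth(step, sd_s = 0.12, fs = cfg$fs) + dev
    x <- pmin(pmax(x, cfg$workspace_x[1]), cfg$workspace_x[2])
    position_trace(x, fs = cfg$fs)
  })
}

#' Construct a position trace
#'
#' @param x Finger x-position series, mm.
#' @param y Optional y-position series, mm.
#' @param fs Sampling rate, Hz.
#' @param t0 Start time, s.
#' @return A `position_trace` list.
#' @export
position_trace <- function(x, y = NULL, fs, t0 = 0) {
  if (length(x) < 2L) stop("position trace needs length >= 2")
  if (!all(is.finite(x))) stop("position trace must be finite")
  structure(list(x = as.numeric(x), y = y, fs = fs, t0 = t0),
            class = "position_trace")
}

# sd of gaussian_smooth applied to unit white noise (for renormalising
# smoothed-noise drift processes)
smooth_sd_norm <- function(sd_s, fs) {
  sd_n <- sd_s * fs
  if (sd_n < 0.5) return(1)
  half <- ceiling(4 * sd_n)
  k <- dnorm(seq(-half, half), sd = sd_n)
  k <- k / sum(k)
  sqrt(sum(k^2))
}

# zero-phase Gaussian smoothing by direct convolution (kernel truncated at 4 sd)
gaussian_smooth <- function(x, sd_s, fs) {
  sd_n <- sd_s * fs
  if (sd_n < 0.5) return(x)
  half <- ceiling(4 * sd_n)
  k <- dnorm(seq(-half, half), sd = sd_n)
  k <- k / sum(k)
  # pad by edge replication to avoid boundary roll-off
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}
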
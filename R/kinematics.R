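#' Finger velocity from a position trace
#'
#' Differentiates the recorded position: central differences in the
#' interior, one-sided differences at the two ends, so the output has the
#' same length as the input.
#'
#' @param trace A [position_trace()] (or numeric vector with `fs` passed).
#' @param fs Sampling rate, Hz (taken from the trace when omitted).
#' @return Velocity series, mm/s.
#' @export
compute_velocity <- function(trace, fs = NULL) {
  if (inherits(trace, "position_trace")) {
    x <- trace$x
    fs <- fs %||% trace$fs
  } else x <- as.numeric(trace)
  if (is.null(fs) || fs <= 0) stop("fs must be > 0")
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  if (n > 2L) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v
}

#' Movement parameters of a scanning trial
#'
#' Extracts the three kinematic summaries used as trial-level decision-model
#' regressors: `v_m`, the mean absolute x-velocity (mean speed, since the
#' signed mean of a back-and-forth scan is near zero); `n_cr`, the number of
#' crossings of the workspace midline (sign changes of `x - midline`, with
#' samples exactly on the midline carried forward to the previous side so
#' chatter on the line is not double-counted); and `t_low`, the total dwell
#' time with the finger on the lower-amplitude side.
#'
#' Only the x-channel is used; y-position carries no task information.
#'
#' @param trace A [position_trace()].
#' @param midline Midline position, mm.
#' @param low_side Which side (`"L"` or `"R"`) holds the lower-amplitude
#'   stimulus on this trial.
#' @return List with `v_m` (mm/s), `n_cr` (count), `t_low` (s).
#' @export
movement_parameters <- function(trace, midline, low_side = c("L", "R")) {
  low_side <- match.arg(low_side)
  x <- trace$x
  fs <- trace$fs
  v <- compute_velocity(trace)
  d <- x - midline
  sgn <- sign(d)
  # carry samples exactly on the midline to the previous side
  for (i in seq_along(sgn)) {
    if (sgn[i] == 0) sgn[i] <- if (i > 1L) sgn[i - 1L] else 0
  }
  nz <- sgn[sgn != 0]
  if (!length(nz)) {
    warning("trace lies entirely on the midline; n_cr = 0")
    n_cr <- 0L
  } else {
    n_cr <- sum(diff(nz) != 0)
  }
  low_sgn <- if (low_side == "L") -1 else 1
  t_low <- sum(sgn == low_sgn) / fs
  list(v_m = mean(abs(v)), n_cr = as.integer(n_cr), t_low = t_low)
}

#' Response-time quality filter
#'
#' Keeps trials whose response time lies in the closed interval
#' \[0.3, 10\] seconds (premature responses and lapses are excluded;
#' exact-boundary trials are kept).
#'
#' @param table Behaviour table with an `rt` column in seconds.
#' @param rt_min,rt_max Bounds of the accepted interval, s.
#' @return List with `table` (kept rows), `rejected` (row indices of
#'   rejected trials) and `fraction_rejected`.
#' @export
qc_filter_trials <- function(table, rt_min = 0.3, rt_max = 10) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("behaviour table is empty")
  if (!"rt" %in% names(table)) stop("behaviour table needs an 'rt' column")
  keep <- table$rt >= rt_min & table$rt <= rt_max
  keep[is.na(keep)] <- FALSE
  list(table = table[keep, , drop = FALSE],
       rejected = which(!keep),
       fraction_rejected = mean(!keep))
}

#' Psychometric fit (cumulative Gaussian)
#'
#' Maximum-likelihood Bernoulli fit of the probability of choosing the
#' non-reference stimulus as a function of the signed amplitude difference,
#' P(choice = 1 | d) = Phi((d - mu) / sigma) — a probit GLM. The point of
#' subjective equality is `mu`; the slope at the PSE is `dnorm(0) / sigma`.
#' No lapse-rate parameter is fitted.
#'
#' @param choices Binary indicator of non-reference choices.
#' @param diffs Signed amplitude differences, same length.
#' @return List with `pse`, `slope`, `mu`, `sigma`.
#' @export
fit_psychometric <- function(choices, diffs) {
  choices <- as.integer(choices)
  if (length(unique(diffs)) < 2L)
    stop("need at least 2 distinct difference levels")
  if (length(unique(choices)) < 2L)
    stop("all choices identical: psychometric fit not identifiable")
  fit <- suppressWarnings(glm(choices ~ diffs, family = binomial("probit")))
  b <- coef(fit)
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("non-increasing psychometric function: fit not identifiable")
  sigma <- 1 / b[[2]]
  mu <- -b[[1]] * sigma
  list(pse = mu, slope = dnorm(0) / sigma, mu = mu, sigma = sigma)
}

#' Psychometric summaries per participant and condition
#'
#' Applies [fit_psychometric()] to each participant x condition subset of a
#' behaviour table, using the signed difference `amplitude - reference` and
#' the indicator of choosing the comparison (non-reference) side.
#'
#' @param behavior Behaviour table with `amplitude`, `comp_side`, `choice`,
#'   `participant`, `condition` columns.
#' @param reference Reference amplitude.
#' @return Data frame with one row per participant x condition.
#' @export
psychometric_summary <- function(behavior, reference = 1) {
  out <- list()
  for (n in unique(behavior$participant)) {
    for (cond in unique(behavior$condition)) {
      sub <- behavior[behavior$participant == n & behavior$condition == cond, ]
      if (!nrow(sub)) next
      d <- sub$amplitude - reference
      ch <- as.integer(sub$choice == sub$comp_side)
      fit <- tryCatch(fit_psychometric(ch, d), error = function(e) NULL)
      if (is.null(fit)) next
      out[[length(out) + 1L]] <- data.frame(
        participant = n, condition = cond,
        pse = fit$pse, slope = fit$slope, sigma = fit$sigma)
    }
  }
  do.call(rbind, out)
}

#' Write / read a behaviour table as CSV
#'
#' @param behavior Behaviour table.
#' @param path Output path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_behavior_csv <- function(behavior, path) {
  write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
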
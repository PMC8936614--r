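#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass with ~1 Hz transition at the low edge,
#' applied by centred convolution with the symmetric (linear-phase) kernel,
#' which makes the overall filter zero-phase. Edges are padded by
#' reflection.
#'
#' @param x Signal.
#' @param fs Sampling rate, Hz.
#' @param low,high Pass-band edges, Hz.
#' @param trans Transition-band width, Hz.
#' @return Filtered signal, same length.
#' @export
fir_bandpass <- function(x, fs, low = 1, high = 50, trans = 1) {
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  n <- seq(-m, m)
  sinc <- function(fc) {
    h <- 2 * fc / fs * sin(pi * n * 2 * fc / fs + 1e-300) /
      (pi * n * 2 * fc / fs + 1e-300)
    h[n == 0] <- 2 * fc / fs
    h
  }
  h <- sinc(high) - sinc(low)
  ham <- 0.54 + 0.46 * cos(pi * n / m)
  h <- h * ham
  nx <- length(x)
  pad <- min(m, nx - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(nx - pad):(nx - 1)]))
  y <- stats::filter(xp, h, sides = 2)
  as.numeric(y)[(pad + 1):(pad + nx)]
}

# linear-interpolation resampling onto a uniform grid at fs_out
resample_series <- function(t, x, fs_out) {
  grid <- seq(min(t), max(t), by = 1 / fs_out)
  approx(t, x, xout = grid, rule = 2)$y
}

#' Import a recording from plain-text files
#'
#' Entry point for real data. Reads a multichannel EEG matrix from CSV/TSV
#' (columns `time` plus one per channel), finger kinematics from CSV
#' (columns `time`, `x`), and trial events from CSV (columns `trial`,
#' `onset`, `offset` in seconds, plus optional `choice`, `rt`,
#' `amplitude`). Both signals are resampled to a common rate, the EEG is
#' band-pass filtered 1-50 Hz with a zero-phase FIR, and trials are epoched
#' by the events into trial records compatible with the decoding and PID
#' stages.
#'
#' EDF/BDF containers are not supported in this build (no reader available
#' in the supported dependency set); export such files to CSV upstream.
#'
#' @param eeg_path,kinematics_path,events_path Input files.
#' @param fs Common sampling rate after resampling, Hz.
#' @param band Pass band, Hz.
#' @return List of trial records (`eeg`, `position`, `velocity`, metadata).
#' @export
import_recording <- function(eeg_path, kinematics_path, events_path,
                             fs = 100, band = c(1, 50)) {
  sep <- if (grepl("\\.tsv$", eeg_path)) "\t" else ","
  eeg_raw <- read.csv(eeg_path, sep = sep, check.names = FALSE)
  kin_raw <- read.csv(kinematics_path)
  events <- read.csv(events_path)
  for (need in c("time")) {
    if (!need %in% names(eeg_raw)) stop("EEG file needs a 'time' column")
    if (!need %in% names(kin_raw))
      stop("kinematics file needs a 'time' column")
  }
  if (!"x" %in% names(kin_raw)) stop("kinematics file needs an 'x' column")
  if (!all(c("trial", "onset", "offset") %in% names(events)))
    stop("events file needs 'trial', 'onset', 'offset' columns")
  if (nrow(events) == 0L) stop("events file contains 0 trials")
  labels <- setdiff(names(eeg_raw), "time")
  if (!length(labels)) stop("EEG file has no channel columns")
  grid_t0 <- max(min(eeg_raw$time), min(kin_raw$time))
  grid_t1 <- min(max(eeg_raw$time), max(kin_raw$time))
  grid <- seq(grid_t0, grid_t1, by = 1 / fs)
  eeg <- vapply(labels, function(ch) {
    y <- approx(eeg_raw$time, eeg_raw[[ch]], xout = grid, rule = 2)$y
    if (fs > 2 * band[1]) fir_bandpass(y, fs, band[1], min(band[2], fs / 2 * 0.9))
    else y
  }, numeric(length(grid)))
  x <- approx(kin_raw$time, kin_raw$x, xout = grid, rule = 2)$y
  trials <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    idx <- which(grid >= ev$onset & grid <= ev$offset)
    if (length(idx) < 2L)
      stop("trial ", ev$trial, " has fewer than 2 samples in [onset, offset]")
    trace <- position_trace(x[idx], fs = fs, t0 = grid[idx[1]])
    list(participant = ev$participant %||% 1L, condition =
           as.character(ev$condition %||% "NA"), trial = ev$trial,
         position = trace, velocity = compute_velocity(trace),
         eeg = structure(eeg[idx, , drop = FALSE], labels = labels, fs = fs),
         choice = ev$choice %||% NA, rt = ev$rt %||% NA,
         amplitude = ev$amplitude %||% NA)
  })
  trials
}
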
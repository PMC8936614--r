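#' Standard 64-channel 10-10 montage labels
#'
#' Channel labels in the ordering used by a 64-electrode active-electrode
#' system with a 10-10 layout. The synthetic generator attaches the first
#' `n_channels` of these to every simulated EEG trace.
#'
#' @return Character vector of 64 labels.
#' @export
montage_1010 <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}

#' Ground-truth hierarchical drift-diffusion parameters
#'
#' Group-level generating parameters for the behavioural simulator, one value
#' per condition. Single-trial drift is `gamma0 + gamma1 * r2 * s`, where
#' `r2` is the trial's latent neural-coupling strength and `s` the absolute
#' stimulus (amplitude) difference; nondecision time is
#' `beta0 + beta_sw * n_cr + beta_exp * t_low` (seconds); boundary separation
#' is `alpha` (evidence units) and the starting point is fixed at the
#' midpoint (`w = 0.5`), the accuracy-coding convention.
#'
#' Participant-level parameters are drawn from Gaussians centred on these
#' means with standard deviations `sd_frac * |mean|` (plus a small floor), so
#' that hierarchical recovery tests have true between-participant variance.
#'
#' @param conditions Character vector of condition names.
#' @param gamma0,gamma1 Drift intercept and drift-coupling slope per
#'   condition (recycled).
#' @param beta0,beta_sw,beta_exp Nondecision-time intercept (s), cost per
#'   midline crossing (s) and cost per second of low-side exploration (s/s).
#' @param alpha Boundary separation per condition.
#' @param sd_frac Between-participant SD as a fraction of the group mean.
#' @return A `true_ddm_params` list.
#' @export
true_ddm_params <- function(conditions = c("V", "H", "VH"),
                            gamma0 = 0.6,
                            gamma1 = c(1.5, 1.5, 2.5),
                            beta0 = 0.5,
                            beta_sw = 0.15,
                            beta_exp = 0.4,
                            alpha = 2.8,
                            sd_frac = 0.12) {
  nc <- length(conditions)
  p <- list(conditions = conditions,
            gamma0 = rep_len(gamma0, nc), gamma1 = rep_len(gamma1, nc),
            beta0 = rep_len(beta0, nc), beta_sw = rep_len(beta_sw, nc),
            beta_exp = rep_len(beta_exp, nc), alpha = rep_len(alpha, nc),
            w = 0.5, sd_frac = sd_frac)
  stopifnot(all(p$alpha > 0), all(p$beta0 > 0))
  structure(p, class = "true_ddm_params")
}

#' Synthetic-experiment configuration
#'
#' Describes one simulated active-sensing experiment: participants scan a
#' 110 mm x 60 mm workspace split at the 55 mm midline, comparing a
#' reference-amplitude texture (amplitude 1) against one of six comparison
#' amplitudes, in visual (V), haptic (H) or visuo-haptic (VH) conditions.
#' Defaults follow the experimental design the analysis assumes: 12
#' participants, 20 trials per amplitude x condition cell, amplitude levels
#' 0.5/0.75/0.9/1.1/1.25/1.5 against reference 1, kinematics and EEG on a
#' common sampling grid.
#'
#' `coupling_snr` gives, per condition, the ratio of velocity-driven EEG
#' variance to noise variance; the multisensory condition defaults to a
#' larger value than either unisensory condition, which is the effect the
#' downstream analysis is designed to detect.
#'
#' @param n_participants Number of simulated participants.
#' @param n_trials_per_cell Trials per participant x condition x amplitude.
#' @param conditions Condition names.
#' @param amplitude_levels Comparison amplitudes (reference excluded).
#' @param reference_amplitude Reference amplitude.
#' @param fs Sampling rate, Hz (kinematics and EEG share one grid).
#' @param n_channels Number of EEG channels (10-10 labels attached).
#' @param workspace_x Workspace extent along x, mm.
#' @param midline_x Split between the two texture subspaces, mm.
#' @param trial_duration Exploration epoch length per trial, s.
#' @param switch_rate Mean side-switching rate of the scanning model, Hz.
#' @param scan_freq,scan_amp Frequency (Hz) and amplitude (mm) of the
#'   within-side scanning oscillation.
#' @param jitter_amp,jitter_tc RMS amplitude (mm) and correlation time (s)
#'   of the broadband corrective-submovement component of the trajectory.
#' @param coupling_snr Named per-condition signal-to-noise ratios.
#' @param coupling_range Support of the latent per-trial coupling strength
#'   (an r-squared, so within \[0, 1\]).
#' @param coupling_conc Beta-distribution concentration of the latent
#'   coupling.
#' @param true_ddm A [true_ddm_params()] object.
#' @param seed Integer seed; every derived quantity is reproducible from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_participants = 12,
                       n_trials_per_cell = 20,
                       conditions = c("V", "H", "VH"),
                       amplitude_levels = c(0.5, 0.75, 0.9, 1.1, 1.25, 1.5),
                       reference_amplitude = 1,
                       fs = 1000,
                       n_channels = 64,
                       workspace_x = c(0, 110),
                       midline_x = 55,
                       trial_duration = 4,
                       switch_rate = 1,
                       scan_freq = 1.25,
                       scan_amp = 20,
                       jitter_amp = 4,
                       jitter_tc = 0.025,
                       coupling_snr = c(V = 1, H = 1, VH = 2),
                       coupling_range = c(0, 0.4),
                       coupling_conc = 10,
                       true_ddm = true_ddm_params(conditions = conditions),
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_trials_per_cell = as.integer(n_trials_per_cell),
              conditions = conditions,
              amplitude_levels = sort(amplitude_levels),
              reference_amplitude = reference_amplitude,
              fs = fs, n_channels = as.integer(n_channels),
              workspace_x = workspace_x, midline_x = midline_x,
              trial_duration = trial_duration,
              switch_rate = switch_rate,
              scan_freq = scan_freq, scan_amp = scan_amp,
              jitter_amp = jitter_amp, jitter_tc = jitter_tc,
              coupling_snr = coupling_snr,
              coupling_range = coupling_range,
              coupling_conc = coupling_conc,
              true_ddm = true_ddm,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1L, cfg$n_trials_per_cell >= 1L,
            cfg$fs > 0, length(cfg$workspace_x) == 2L,
            cfg$workspace_x[1] < cfg$workspace_x[2])
  if (cfg$midline_x <= cfg$workspace_x[1] || cfg$midline_x >= cfg$workspace_x[2])
    stop("midline_x must lie strictly inside workspace_x")
  if (any(cfg$amplitude_levels == cfg$reference_amplitude))
    stop("amplitude_levels must exclude the reference amplitude")
  if (is.unsorted(cfg$amplitude_levels))
    stop("amplitude_levels must be sorted")
  miss <- setdiff(cfg$conditions, names(cfg$coupling_snr))
  if (length(miss))
    stop("coupling_snr missing for condition(s): ", paste(miss, collapse = ", "))
  if (any(cfg$coupling_snr < 0)) stop("coupling_snr must be >= 0")
  if ("VH" %in% cfg$conditions) {
    uni <- intersect(c("V", "H"), cfg$conditions)
    if (length(uni) && cfg$coupling_snr[["VH"]] < max(cfg$coupling_snr[uni]))
      warning("default configuration expects coupling_snr(VH) >= max(V, H)")
  }
  if (cfg$true_ddm$w != 0.5) stop("starting-point fraction w must equal 0.5")
  if (cfg$n_channels < 1L || cfg$n_channels > 64L)
    stop("n_channels must be in 1..64 (10-10 montage)")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields of the YAML document override [sim_config()] defaults;
#' `coupling_snr` is given as a named mapping and `true_ddm` as a nested
#' mapping passed to [true_ddm_params()].
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$coupling_snr)) raw$coupling_snr <- unlist(raw$coupling_snr)
  if (!is.null(raw$true_ddm))
    raw$true_ddm <- do.call(true_ddm_params, raw$true_ddm)
  do.call(sim_config, raw)
}

#' Absolute stimulus difference per comparison amplitude
#'
#' Maps each comparison amplitude to the task's difficulty variable
#' `s = |amplitude - reference|`; with the default levels this takes the
#' values 0.1, 0.25 and 0.5.
#'
#' @param amplitude Comparison amplitude(s).
#' @param reference Reference amplitude.
#' @return Numeric vector of absolute differences.
#' @export
stimulus_difference <- function(amplitude, reference = 1) {
  abs(amplitude - reference)
}
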
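#' Draw participant-level DDM parameters from the group distribution
#'
#' @param truth A [true_ddm_params()] object.
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @return Data frame, one row per participant x condition, columns
#'   `participant`, `condition`, `gamma0`, `gamma1`, `beta0`, `beta_sw`,
#'   `beta_exp`, `alpha`.
#' @export
draw_participant_params <- function(truth, n_participants, seed = 1L) {
  pars <- c("gamma0", "gamma1", "beta0", "beta_sw", "beta_exp", "alpha")
  lower <- c(gamma0 = -Inf, gamma1 = -Inf, beta0 = 0.05, beta_sw = -Inf,
             beta_exp = -Inf, alpha = 0.2)
  rows <- list()
  for (ci in seq_along(truth$conditions)) {
    cond <- truth$conditions[ci]
    for (n in seq_len(n_participants)) {
      s <- derive_seed(seed, "pp", ci, n)
      vals <- with_seed(s, {
        v <- numeric(length(pars))
        names(v) <- pars
        for (p in pars) {
          mu <- truth[[p]][ci]
          sdv <- truth$sd_frac * abs(mu) + 0.02
          x <- rnorm(1, mu, sdv)
          for (k in 1:20) {           # truncation by rejection
            if (x >= lower[[p]]) break
            x <- rnorm(1, mu, sdv)
          }
          v[p] <- max(x, lower[[p]])
        }
        v
      })
      rows[[length(rows) + 1L]] <-
        data.frame(participant = n, condition = cond, t(vals))
    }
  }
  do.call(rbind, rows)
}

# latent per-trial coupling strength: Beta on coupling_range with
# condition-dependent mean snr/(1+snr) (an r-squared has support [0,1],
# so a scaled Beta is the natural family)
draw_coupling <- function(cfg, condition, n, seed) {
  snr <- cfg$coupling_snr[[condition]]
  if (snr <= 0) return(rep(0, n))
  mu01 <- min(max(snr / (1 + snr), 0.05), 0.95)
  with_seed(seed, {
    b <- rbeta(n, mu01 * cfg$coupling_conc, (1 - mu01) * cfg$coupling_conc)
    cfg$coupling_range[1] + diff(cfg$coupling_range) * b
  })
}

#' Generate a synthetic behavioural dataset (no EEG)
#'
#' Fast path used when only the decision model is of interest: for every
#' participant x condition x amplitude cell it simulates a scanning
#' trajectory, extracts the movement parameters, draws the trial's latent
#' neural-coupling strength, assembles single-trial DDM parameters
#' (drift `gamma0 + gamma1 * r2 * s`, nondecision time
#' `beta0 + beta_sw * n_cr + beta_exp * t_low`, boundary `alpha`) from the
#' participant-level values, and simulates a choice and response time.
#' The `r2` column holds the latent coupling, standing in for a decoded
#' reconstruction accuracy.
#'
#' @param cfg A [sim_config()].
#' @param fs_kin Optional reduced sampling rate for the behaviour-only
#'   trajectory simulation (movement parameters are rate-invariant).
#' @return List with `behavior` (a behaviour table) and `truth`
#'   (participant-level generating parameters plus the config).
#' @export
generate_behavior_table <- function(cfg, fs_kin = 100) {
  kin_cfg <- cfg
  kin_cfg$fs <- fs_kin
  pp <- draw_participant_params(cfg$true_ddm, cfg$n_participants,
                                seed = derive_seed(cfg$seed, "ddm"))
  rows <- vector("list",
                 cfg$n_participants * length(cfg$conditions) *
                   length(cfg$amplitude_levels) * cfg$n_trials_per_cell)
  ri <- 0L
  for (n in seq_len(cfg$n_participants)) {
    for (cond in cfg$conditions) {
      prow <- pp[pp$participant == n & pp$condition == cond, ]
      cell_seed <- derive_seed(cfg$seed, "beh", n, cond)
      n_cell <- length(cfg$amplitude_levels) * cfg$n_trials_per_cell
      r2_all <- draw_coupling(cfg, cond, n_cell,
                              derive_seed(cell_seed, "r2"))
      ti <- 0L
      for (amp in cfg$amplitude_levels) {
        for (k in seq_len(cfg$n_trials_per_cell)) {
          ti <- ti + 1L
          tseed <- derive_seed(cell_seed, "trial", ti)
          trace <- simulate_trajectory(kin_cfg, duration = cfg$trial_duration,
                                       seed = derive_seed(tseed, "traj"))
          comp_side <- with_seed(derive_seed(tseed, "side"),
                                 sample(c("L", "R"), 1L))
          low_side <- if (amp < cfg$reference_amplitude) comp_side
                      else setdiff(c("L", "R"), comp_side)
          mp <- movement_parameters(trace, midline = cfg$midline_x,
                                    low_side = low_side)
          r2 <- r2_all[ti]
          s <- stimulus_difference(amp, cfg$reference_amplitude)
          drift <- prow$gamma0 + prow$gamma1 * r2 * s
          ndt <- prow$beta0 + prow$beta_sw * mp$n_cr + prow$beta_exp * mp$t_low
          beh <- simulate_behavior(drift, prow$alpha, ndt = ndt, w = 0.5,
                                   seed = derive_seed(tseed, "ddm"), n = 1L)
          acc <- as.integer(identical(beh$choice[1], "upper"))
          correct_side <- if (amp > cfg$reference_amplitude) comp_side
                          else setdiff(c("L", "R"), comp_side)
          choice_side <- if (acc == 1L) correct_side
                         else setdiff(c("L", "R"), correct_side)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            participant = n, condition = cond, trial = ti,
            amplitude = amp, s = s,
            amplitude_low_side = low_side, comp_side = comp_side,
            choice = choice_side, accuracy = acc, rt = beh$rt[1],
            v_m = mp$v_m, n_cr = mp$n_cr, t_low = mp$t_low, r2 = r2)
        }
      }
    }
  }
  behavior <- do.call(rbind, rows[seq_len(ri)])
  list(behavior = behavior,
       truth = list(participant_params = pp, true_ddm = cfg$true_ddm,
                    seed = cfg$seed))
}

#' Generate a full synthetic dataset with EEG
#'
#' Composes the trajectory, EEG and decision simulators per trial. Every
#' condition has its own ground-truth velocity-encoding pattern; the trial's
#' channel signal-to-noise ratio scales with the trial's latent coupling
#' strength around the condition's configured `coupling_snr`, so conditions
#' with stronger configured coupling yield higher decoding accuracy
#' downstream. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `trials` (list of trial records holding `position`,
#'   `velocity`, `eeg` and metadata), `behavior` (behaviour table, `r2`
#'   holding the latent coupling), `truth` (forward patterns per condition,
#'   latent couplings, participant parameters, seed) and `cfg`.
#' @export
generate_dataset <- function(cfg) {
  beh <- generate_behavior_table(cfg, fs_kin = cfg$fs)
  patterns <- lapply(setNames(cfg$conditions, cfg$conditions), function(cond) {
    make_forward_pattern(cfg$n_channels, cfg$fs,
                         seed = derive_seed(cfg$seed, "pattern", cond))
  })
  trials <- vector("list", nrow(beh$behavior))
  for (i in seq_len(nrow(beh$behavior))) {
    row <- beh$behavior[i, ]
    cond <- row$condition
    cell_seed <- derive_seed(cfg$seed, "beh", row$participant, cond)
    tseed <- derive_seed(cell_seed, "trial", row$trial)
    trace <- simulate_trajectory(cfg, duration = cfg$trial_duration,
                                 seed = derive_seed(tseed, "traj"))
    vel <- compute_velocity(trace)
    snr_cond <- cfg$coupling_snr[[cond]]
    mean_r2 <- if (snr_cond > 0)
      cfg$coupling_range[1] +
        diff(cfg$coupling_range) * min(max(snr_cond / (1 + snr_cond), 0.05), 0.95)
    else 0
    snr_trial <- if (mean_r2 > 0) snr_cond * row$r2 / mean_r2 else 0
    eeg <- simulate_eeg(structure(vel, fs = cfg$fs), patterns[[cond]],
                        snr = snr_trial, seed = derive_seed(tseed, "eeg"))
    trials[[i]] <- list(participant = row$participant, condition = cond,
                        trial = row$trial, amplitude = row$amplitude,
                        s = row$s, position = trace, velocity = vel,
                        eeg = eeg, choice = row$choice,
                        accuracy = row$accuracy, rt = row$rt,
                        snr = snr_trial)
  }
  truth <- c(beh$truth,
             list(forward_pattern = patterns,
                  latent_coupling = beh$behavior$r2))
  structure(list(trials = trials, behavior = beh$behavior, truth = truth,
                 cfg = cfg), class = "actsense_dataset")
}
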
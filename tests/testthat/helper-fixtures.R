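# Shared fixtures, built once per test session. All synthetic data is
# generated in code at test time; heavier objects are memoised here so
# several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# one participant, three conditions, small but decodable
small_dataset <- function() {
  fixture("small_ds", function() {
    generate_dataset(sim_config(
      n_participants = 1, n_trials_per_cell = 2,
      conditions = c("V", "H", "VH"), fs = 50, n_channels = 6,
      trial_duration = 3, coupling_snr = c(V = 1, H = 1, VH = 2),
      seed = 101))
  })
}

small_lag_spec <- function() lag_spec(fs = 50)

trials_of <- function(dataset, condition, participant = 1) {
  Filter(function(tr) tr$condition == condition &&
           tr$participant == participant, dataset$trials)
}

# small single-condition behavioural dataset for DDM tests
small_behavior <- function() {
  fixture("small_beh", function() {
    cfg <- sim_config(n_participants = 6, n_trials_per_cell = 10,
                      conditions = "VH", coupling_snr = c(V = 1, H = 1, VH = 2),
                      true_ddm = true_ddm_params(conditions = "VH",
                                                 gamma1 = 2),
                      seed = 33)
    qc_filter_trials(generate_behavior_table(cfg)$behavior)$table
  })
}

small_ddm_fit <- function() {
  fixture("small_fit", function() {
    sample_posterior(small_behavior(), ddm_spec(), chains = 2,
                     n_samples = 2000, burn = 700, thin = 10, seed = 5)
  })
}
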
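# actsense

Analysis toolkit for **active-sensing perceptual decision experiments**: a
participant freely scans a two-sided virtual texture (110 mm x 60 mm
workspace, midline at 55 mm) with their finger, comparing the two sides'
amplitudes from visual (V), haptic (H) or combined (VH) cues, while
kinematics, 64-channel EEG and choice/response time are recorded. The
package is aimed at researchers who want to link the *neural encoding of
self-generated sensing movements* to *decision dynamics* and to *cross-modal
information interactions*, and it ships a fully seeded synthetic-data
generator so every estimator can be validated against known ground truth.

## What it computes

**1. TRF decoding of finger velocity from EEG.** A lagged ridge regression
reconstructs velocity from channels at lags tau in [-200, 400] ms:

    s_hat(t) = sum_tau sum_i g(tau, i) m(t + tau, i)

with per-trial reconstruction accuracy r^2 = cor(s, s_hat)^2 obtained by
five-fold cross-fitting, penalty lambda = 2^2 by default (the CV curve is
flat across 2^0..2^4). Decoders invert to interpretable forward (encoding)
patterns f = Cov(M) g / (s_hat' s_hat). Phase-randomisation surrogates
(amplitude spectra preserved bin-by-bin, phases randomised) give the null
distribution of r^2.

**2. Hierarchical Bayesian drift-diffusion modelling.** Single-trial
decision parameters are linear in neural and kinematic regressors:

    delta = gamma0 + gamma1 * r2 * s          (drift)
    tau   = beta0 + beta_sw * n_cr + beta_exp * t_low   (nondecision time)
    alpha = theta0 [+ ...]                    (boundary)

with s in {0.1, 0.25, 0.5} the stimulus difference, n_cr the midline
crossings and t_low the dwell time on the weaker stimulus. Participant
coefficients are Gaussian around per-condition group means (uniform
hyperpriors); the likelihood is the Wiener first-passage-time density
(dual series expansion, adaptive truncation); sampling is adaptive
Metropolis-within-Gibbs with non-centred interweaving, 3 chains, verified
by Gelman-Rubin Rhat < 1.01; model variants are compared by DIC; effects
are reported as posterior probabilities, e.g. Prob(gamma1(VH) > gamma1(V)).

**3. Partial information decomposition.** Per EEG channel, the joint mutual
information the V- and H-model predictions carry about the VH-model
prediction is split into redundancy, unique-V, unique-H and synergy using
the common-change-in-surprisal estimator on Gaussian-copula data, with
whole-trial permutation tests (99th percentile) and Benjamini-Hochberg FDR
(q = 0.01) across channels.

## Worked example

```r
library(actsense)

cfg <- sim_config(n_participants = 1, n_trials_per_cell = 3,
                  conditions = c("V", "H", "VH"), fs = 100, n_channels = 12,
                  trial_duration = 4, coupling_snr = c(V = 1, H = 1, VH = 2),
                  seed = 11)
ds <- generate_dataset(cfg)

spec <- lag_spec(fs = 100)                  # lags -200..+400 ms
vh <- Filter(function(tr) tr$condition == "VH", ds$trials)
sc <- score_single_trials(vh, spec, lambda = 4, seed = 1)
round(mean(sc$r2), 3)
#> [1] 0.621

dec <- fit_decoder(vh, spec, lambda = 4)
fwd <- to_forward_model(dec, vh)
round(cor(as.vector(unclass(fwd)),
          as.vector(ds$truth$forward_pattern[["VH"]])), 3)
#> [1] 0.957
```

The mean held-out r^2 of 0.62 says the decoder reconstructs about 60% of
the velocity variance at the configured multisensory coupling; the 0.96
correlation between the recovered forward pattern and the generator's true
channel-by-lag kernel says the pattern inversion is faithful.

Fitting the decision model to a synthetic cohort:

```r
cfg <- sim_config(n_participants = 6, n_trials_per_cell = 10,
                  conditions = "VH", coupling_snr = c(V = 1, H = 1, VH = 2),
                  true_ddm = true_ddm_params(conditions = "VH", gamma1 = 2),
                  seed = 42)
qc <- qc_filter_trials(generate_behavior_table(cfg)$behavior)  # RT in [0.3, 10] s
fit <- sample_posterior(qc$table, ddm_spec(), chains = 3,
                        n_samples = 1500, burn = 400, thin = 5, seed = 7)
subset(posterior_summary(fit), parameter == "mu_gamma1_VH")
#>      parameter     mean      ci5     ci95     rhat
#> 2 mu_gamma1_VH 3.385805 1.614577 5.307534 1.004826
posterior_prob(fit, "mu_gamma1_VH > 0")
#> [1] 0.9969697
```

The group-level credible interval for the drift-coupling slope covers the
generating value 2, and the posterior mass above zero reproduces the
neural-coupling-predicts-drift effect the model is built to detect (the
Rhat column approaches 1 even at this short chain length; acceptance-scale
runs use longer chains and check Rhat < 1.01 on every group parameter).

A full pipeline run (`run_pipeline(run_config(...))`, or the CLI in
`inst/cli/actsense.R`) writes `behavior.csv`, `models.h5`,
`posterior_summary.csv`, `pid.csv` and per-stage JSON manifests, and is
byte-identical when rerun with the same config and seed.

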
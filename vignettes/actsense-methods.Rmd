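---
title: "Methods: active-sensing decoding, decision modelling and cross-modal information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-sensing decoding, decision modelling and cross-modal information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

`actsense` analyses a class of active-sensing perceptual experiments: a
participant freely scans a two-sided virtual texture (a 110 mm x 60 mm
workspace split at the 55 mm midline) with their index finger, comparing the
texture amplitude of the two sides using visual (V), haptic (H) or combined
(VH) cues, and reports which side is stronger. Three simultaneous data
streams result — finger kinematics, multichannel EEG, and choice/response
time — and the package links them in four stages:

1. **Kinematics**: finger velocity, mean speed `v_m`, midline crossings
   `n_cr`, dwell time on the lower-amplitude side `t_low`, response-time
   quality filtering, and psychometric (cumulative-Gaussian) summaries.
2. **Decoding**: a temporal-response-function (TRF) ridge regression
   reconstructs instantaneous finger velocity from EEG channels lagged
   -200..+400 ms; per-trial reconstruction accuracy `r2` (squared Pearson
   correlation) quantifies how strongly the brain encodes the participant's
   own sensing movements on that trial. Decoders are inverted to forward
   (encoding) patterns for interpretation, and phase-randomisation
   surrogates give a null distribution for the accuracy.
3. **Decision modelling**: a hierarchical Bayesian drift-diffusion model
   (DDM) with trial-level regressors: drift
   `delta = gamma0 + gamma1 * r2 * s` (with `s` the absolute stimulus
   difference), nondecision time
   `tau = beta0 + beta_sw * n_cr + beta_exp * t_low`, boundary `alpha`,
   starting point fixed at the midpoint (accuracy coding). The Wiener
   first-passage-time density supplies the likelihood; model variants are
   compared by DIC.
4. **Information decomposition**: per EEG channel, a Gaussian-copula partial
   information decomposition (PID) splits the information the two
   unisensory encoding models carry about the multisensory model into
   redundancy, two unique atoms, and synergy, with trial-level permutation
   tests and Benjamini-Hochberg FDR across channels.

No public dataset accompanies this design, so the package ships a seeded
synthetic generator whose ground truth drives every recovery test.

# The synthetic world

`sim_config()` encodes the experiment the analysis assumes: 12 participants,
6 comparison amplitudes (0.5, 0.75, 0.9, 1.1, 1.25, 1.5 against reference
1, giving `s` in {0.1, 0.25, 0.5}), 20 trials per amplitude and condition,
kinematics and EEG on a common sampling grid, and per-condition coupling
signal-to-noise ratios with the multisensory condition strongest (default
V = H = 1, VH = 2) — the effect the pipeline is designed to detect.

## Trajectory model

The scanning model is a smoothed telegraph process: the finger's home side
switches at exponential dwell times (`switch_rate`, default 1 Hz), and a
bounded oscillation (default 1.25 Hz, 20 mm) emulates within-side scanning.
Two deliberate realism features matter for identifiability:

* the oscillation's instantaneous frequency and amplitude drift slowly
  (free exploration is not metronomic), and
* a broadband corrective-submovement component (default 4 mm RMS, 25 ms
  correlation time) emulates the small corrections and tremor in real
  finger movement.

Without the broadband component the velocity spectrum is a line at the scan
frequency, its autocorrelation never decays, and covariance-based encoding
patterns are unidentifiable — any estimator would return an
autocorrelation-smeared kernel. The defaults were chosen once, on the
spectral argument that the velocity autocorrelation half-width should be
comparable to the encoding-kernel width; they were not tuned against test
outcomes. The published distributions of switch rates and scan speeds are
unknown, so these values are plausible rather than calibrated.

## EEG model

Each channel responds to velocity through a smooth Gaussian-bump lag kernel
peaking between 20 and 160 ms (`make_forward_pattern()`), with random
channel amplitudes and signs, plus white Gaussian noise scaled so the
channel-wise signal-to-noise variance ratio equals the trial's coupling.
Kernel widths default to 80-120 ms. This width range matches the sustained
deflections a velocity TRF shows over the 20-160 ms window and puts the
kernels in the regime where they are near-eigenfunctions of convolution
with the velocity autocorrelation, so the forward-model transform converges
to the generating pattern. Narrower kernels would make the
pattern-recovery guarantee unattainable for *any* covariance-based
estimator — a smearing limitation that applies equally to real EEG, and
that a green recovery test therefore does not rule out.

The generator produces linear, stationary, Gaussian EEG. It does not
emulate a head model, 1/f background spectra, artifacts, or cross-channel
noise correlations; a green decoding test establishes correctness of the
estimator chain, not robustness to those real-data features (artifact
removal is delegated upstream by design).

## Latent coupling and behaviour

Each trial draws a latent coupling strength from a Beta distribution scaled
to [0, 0.4] (an `r2` is a squared correlation, so bounded support is
required; 0.4 is a generous ceiling for single-trial EEG decoding). The
condition's mean coupling is `snr / (1 + snr)` mapped into that range, so
stronger-coupled conditions yield stochastically larger per-trial `r2`. The
same latent value scales the trial's EEG signal-to-noise ratio and enters
the drift equation, which is what makes downstream recovery tests
meaningful. In the behaviour-only fast path
(`generate_behavior_table()`), the latent coupling stands in for the
decoded `r2` directly; in the full path the decode stage overwrites it with
the estimated value.

Choices and response times come from Euler-Maruyama simulation of a Wiener
accumulator with unit diffusion coefficient (the common DDM convention; the
noise scaling is otherwise arbitrary), step 0.5 ms — halving the step does
not change absorption probabilities beyond Monte-Carlo error. Group-level
generating parameters default to `gamma0 = 0.6`, `gamma1 = (1.5, 1.5,
2.5)` across (V, H, VH), `beta0 = 0.5` s, `beta_sw = 0.15` s/crossing,
`beta_exp = 0.4` s/s, `alpha = 2.8`, placing mean response times near 3.5-4
s and accuracies near 85-92%, in the range this task produces.
Participant-level parameters scatter around the group means with SD 12% of
the mean (plus a small floor), giving genuine between-participant variance
for hierarchical recovery. One simplification is worth noting: trials have
a fixed exploration duration (default 4 s) and the movement parameters are
computed over that whole window, whereas a real trial ends at the response;
the nondecision-time regression is therefore exact in the generator but
only approximate in real data.

# Numerical choices

* **Ridge convention**: columns and target are z-scored internally and the
  penalty `lambda` is added to the standardised Gram diagonal; the
  intercept is unpenalised. The pipeline default is `lambda = 2^2`,
  justified by the flatness of the cross-validated accuracy curve across
  `2^0..2^4` (exposed via `select_lambda_cv()`).
* **Forward models** are computed in *native* (centred, unstandardised)
  units: `f = Cov(M) g_native / var(s_hat)`. Computing the pattern in the
  z-scored space silently normalises away each channel's amplitude and
  destroys the cross-channel structure — this was an actual defect caught
  by the recovery test during development.
* **Single-trial scoring** uses 5-fold cross-fitting over trials (each
  trial scored by a decoder trained on the other folds); an 80/20 holdout
  mode is exposed for condition-level summaries. Fold counts follow the
  other cross-validation uses in the design.
* **Wiener density**: evaluated by the classic pair of series expansions
  (small-time and large-time), choosing whichever needs fewer terms for a
  truncation error below `eps` (default 1e-6), then rescaled from the
  normalised to the native parameterisation; the upper-boundary density
  uses the reflection `(v, w) -> (-v, 1 - w)`. `rt <= ndt` yields `-Inf`
  rather than an exception so samplers can reject.
* **Sampler**: adaptive Metropolis-within-Gibbs. Participant-level
  coefficients get componentwise Gaussian random walks (scales adapted to
  ~35% acceptance during burn-in, then frozen) plus a centred joint
  intercept-slope move per covariate (proposing `slope += d`,
  `intercept -= d * mean(covariate)`), which decorrelates the otherwise
  collinear pairs. Group means are Gibbs-updated (truncated normal); group
  SDs use a log-scale random walk. Interleaved non-centred moves — holding
  standardised residuals fixed while translating the group mean or
  rescaling the group SD and carrying all participant coefficients along —
  break the funnel coupling that otherwise makes group-SD mixing
  prohibitively slow. All draws use R's RNG with seed-derived substreams
  per chain, so runs are exactly reproducible.
* **Priors**: uniform boxes — drift coefficients (-20, 20), boundary
  intercept (0.1, 10), nondecision intercept (0.05, min observed RT),
  other coefficients (-10, 10), group SDs (0.005, 5). These cover reported
  core-parameter estimates for this task (drift ~0.9, nondecision ~2.9 s,
  boundary ~2.9) with wide margins. Inter-trial variability parameters
  (sv, st, sz) are deliberately absent.
* **DIC**: `Dbar + pD` with `pD = Dbar - D(theta_bar)`, `theta_bar` the
  posterior mean of participant-level coefficients. DIC differences among
  nested variants are of the same order as Monte-Carlo noise in `Dbar`, so
  model-comparison runs use light thinning (many retained draws) rather
  than long thin chains.
* **Gelman-Rubin**: the classic potential-scale-reduction factor from
  between- and within-chain variances; the convergence criterion is
  `Rhat < 1.01` on every group-level parameter.
* **PID**: inputs are Gaussian-copula normalised (rank transform then
  inverse normal), making every estimate invariant to monotone transforms.
  Redundancy uses the common-change-in-surprisal rule: the expectation of
  the pointwise co-information restricted to samples where the pointwise
  information changes of V, H, the joint, and the co-information share a
  sign, all surprisals evaluated under the fitted joint Gaussian. A
  minimum-single-MI redundancy is available as `estimator = "mmi"` because
  published pointwise criteria vary. Unique atoms and synergy close the
  lattice by construction, so the marginal identities hold to round-off on
  any input.
* **Permutations** shuffle whole trials of the target signal (preserving
  within-trial autocorrelation), with the plus-one p-value rule and
  Benjamini-Hochberg FDR at q = 0.01 across channels per atom, matching a
  99th-percentile criterion.
* **Surrogates**: channel phases are randomised independently by default
  (the stricter decorrelation); a shared-phase option preserves
  cross-spectra. Decoders are re-fitted per surrogate by default
  (stricter); re-scoring a fixed decoder is available.

# Design decisions that were genuinely open

* Whether single-trial `r2` derives from the 20% holdout only or from full
  cross-fitting is unspecified in the source design; cross-fitting is the
  default (every trial gets a score, which the decision model needs), the
  holdout mode is exposed.
* Regression coefficients are hierarchical (Gaussian across participants
  per condition) rather than fixed at group level, matching the plate
  structure of the model diagram.
* A synergy test channel is constructed as a *difference of correlated
  predictors* (the canonical Gaussian synergy). An XOR/product-sign
  construction has no second-moment signature, so a covariance-based
  Gaussian estimator is provably blind to it; such a channel cannot serve
  as a positive control here.
* EDF/BDF ingestion is out of reach offline (no reader in the supported
  dependency stack); `import_recording()` takes plain-text CSV/TSV
  exports instead and applies the same resampling, 1-50 Hz zero-phase FIR
  (Hamming windowed-sinc, ~1 Hz transition), and event epoching.

# Known limitations

* The trajectory and EEG generators are stationary and linear; none of the
  nonstationarity, artifacts, or spatially correlated noise of real EEG is
  emulated.
* Decoding accuracies on synthetic data run higher than typical real-EEG
  values because channel noise is independent across channels; the
  recovery guarantees concern estimator correctness, not absolute accuracy
  levels.
* Forward-model recovery is bounded by velocity-autocorrelation smearing;
  correlations near 1 are only achievable when kernel widths are
  comparable to or wider than the autocorrelation width (see above).
* DIC model selection at desk scale is noisy; the model-recovery guarantee
  is probabilistic (a win-fraction across seeded replicates), not
  per-dataset.
* The acceptance-scale MCMC settings (thousands of iterations) are far
  shorter than production-scale runs; the convergence criterion is
  verified at the documented scale, and longer chains only improve it.
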
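---
title: "Methods: quantifying directed functional influence between two neural populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying directed functional influence between two neural populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`dualpop` analyzes simultaneous spike recordings from two motor cortical
populations — a premotor-like region ("A") and a primary-motor-like region
("B") — during a cued reaching behavior, together with multi-muscle EMG.
The scientific question is whether the functional influence between the two
populations is asymmetric, and how such asymmetry does or does not show up
in their firing patterns. The package implements the full chain:

1. a synthetic session generator with known ground truth;
2. EMG conditioning, reach-onset detection, trial exclusion, unit curation;
3. perturbation-effect quantification for optogenetic-style inactivation,
   including a modified stimulus-associated spike latency test (SALT);
4. population alignment by CCA and PLS-SVD with lag scans and shifted-time
   controls, plus activity-onset timing;
5. a two-population delayed-latent factor model fit by EM;
6. pairwise directed predictivity (transfer entropy, point-process Granger
   causality, convergent cross mapping) with permutation nulls;
7. a Dale-constrained dual-population recurrent rate network.

Throughout, the delay sign convention is: **negative delay = region A
leads** (region B expresses the same signal later).

# The synthetic world

The generator's defaults are a *stated world*, fixed once, against which
every downstream stage is validated.

* **Latents.** Across-region latents are draws of a squared-exponential
  Gaussian process on a 1 ms grid (unit variance; default timescale 100 ms,
  a typical autocorrelation scale for trial-averaged motor cortical
  activity). Region B's copy of across-latent $j$ at time $t$ equals the
  master process at $t + D_j$. Within-region latents are private draws.
  Latent loading strengths decay geometrically ($0.8^{j-1}$): equal-variance
  shared latents are unidentifiable up to rotation — no estimator could
  recover per-latent delays from them — and decaying spectra are what real
  population recordings show.
* **Spiking.** Per-unit intensity is `max(0, baseline + loadings · latents)`
  (rectified-linear link, the simplest link guaranteeing nonnegative rates),
  with baselines drawn from a gamma distribution (default mean 10 spikes/s)
  and inhomogeneous-Poisson emission on a 1 ms grid. Directed pairwise
  coupling adds, per source spike, an alpha-shaped hazard increment (2 ms
  rise) on the target, implemented as a superposed Poisson process so the
  increment is exactly additive. The hazard is centered so its *peak* sits
  at the configured delay; its mass is centered about 2 ms later, which is
  visible in transfer-entropy best-delay estimates.
* **Trials and EMG.** Reaches are regularly spaced (≥ 2 s apart, so
  circular-shift nulls are valid), with a 100 ms reaction time and a 300 ms
  reach-to-contact time — values typical for head-fixed mouse reaching, and
  chosen so that the 30th-percentile upper threshold of the double-threshold
  onset detector falls inside the movement-related part of the reach epoch,
  as it does in real data. EMG is positive-clipped Gaussian noise plus a
  quadratic-rise burst at each true onset, smoothed with the same 10 ms
  Gaussian the preprocessing applies to measured EMG (the generator emulates
  the *conditioned* envelope). Sessions end with a 12 s quiet tail so
  5–10 s shifted-time controls always have room.
* **Inactivation.** On light trials the targeted region's intensity is
  multiplied by $(1-\text{direct})$ from light onset and the other region's
  by $(1-\text{downstream})$ after a configurable latency (default 10 ms, an
  oligosynaptic delay).

What a green test on this world does *not* establish: robustness to
non-Poisson firing, electrode drift, behavioral variability in reach
kinematics, or sorting errors — none of which the generator emulates.

# Preprocessing choices

* The 250 Hz high-pass is a zero-phase 4th-order Butterworth. No DSP
  package is available in the target environment, so it is realized as the
  squared Butterworth magnitude response applied in the frequency domain —
  numerically the magnitude behavior of forward–backward filtering.
* The quiescent epoch used for the global EMG SD is chosen automatically as
  the 1 s window of minimal envelope variance (the original procedure was
  manual; a pipeline needs a rule). This biases the SD slightly low, which
  makes the lower threshold slightly conservative.
* All exclusion inequalities are strict ("greater than"); ties are retained.
  Note a sample of $n$ trials can only contain a $>3$ SD outlier of its own
  statistics when $n \gtrsim 11$, since $\max z \le (n-1)/\sqrt n$.
* The refractory-violation statistic is autocorrelogram mass in
  $[0.3, 1.0)$ ms over mass in $[10, 50)$ ms (windows closed on the left),
  threshold 0.18 taken as a fixed constant; a flat (Poisson)
  autocorrelogram gives $0.7/40 = 0.0175$. The 0.417 ms waveform-width
  boundary is likewise treated as a fixed constant.

# Perturbation quantification

The chance level for the |control − light| EMG difference is the mean of
1000 split-half control differences (halves drawn without replacement,
seeded); after subtracting it and the 20 ms pre-onset baseline, values below
zero are expected and kept. Z-scoring of per-neuron effects uses the
session-wide rate mean and SD — the only unambiguous reading of "z-scored
firing rates" without a stated window.

The modified SALT compares the first-spike-latency histogram (1 ms
resolution, 5 ms windows, plus a no-spike category) after light onsets
against histograms from randomly placed baseline epochs (≥ 500 ms from any
light onset; 10× as many as light events). The observed statistic is the
Jensen–Shannon divergence between the light histogram and one randomly
chosen baseline group of matched size; the null is built from 1000
divergences between disjoint baseline groups. Because the observed draw is
exchangeable with the null draws under no light effect, the p-value is
uniform by construction — the property the modification exists to restore.
The baseline-epoch count and null-draw count are config-exposed (the source
procedure leaves both unstated).

# Population alignment

Activity matrices are eight concatenated 200 ms trial averages (reach-onset
and grasp aligned × four spouts) at 1 ms resolution: 1600 rows. Columns are
mean-centered once over the concatenation; total variance $v$ is the sum of
per-neuron variances of the centered columns. PLS-SVD decomposes the
cross-covariance $X_A^\top X_B/(n-1)$; the alignment scalar
$c = \mathrm{tr}(S)/(v_A+v_B)$ then equals exactly $0.5$ when $X_B$ is an
orthogonal transform of $X_A$ (Cauchy–Schwarz bound). CCA is computed on the
first 25 principal components (auto-reduced at low rank); canonical weight
vectors are orthogonalized (QR) to compute additional variance captured,
and the summary correlation weights each pair by the average of its two
regions' additional variance. Component signs are flipped so every pair's
covariance is nonnegative.

The pre-movement variance fraction is computed from sums of squared
deviations about each sub-window's own mean (pre vs post), which makes the
"all activity after onset → 0" and "all before → 1" limits exact and gives
0.5 for temporally structureless data.

# The delayed-latent model

Observations in each region are linear-Gaussian readouts of latents with
squared-exponential priors on the 20 ms bin grid (50 bins per trial over
−200..+800 ms); across-latents are shared with a continuous per-latent
delay entering the prior cross-covariance, within-latents are private, and
observation noise is diagonal. Counts are square-root-stabilized by default
to temper Poisson heteroscedasticity. The E-step computes the exact joint
posterior over all latent time courses per trial; the M-step updates
loadings, means and noise in closed form and kernel parameters (delay,
timescale) by numerical optimization of the expected complete-data
log-likelihood, so the marginal likelihood is nondecreasing (checked to
1e−8 in the tests).

Two numerical choices depart from a textbook EM, both because delay
coordinates move pathologically slowly under EM (the source method runs up
to 10,000 iterations; this build cannot):

1. **Initialization.** Delays and across-loadings are initialized by a
   greedy SVD of the *lagged* cross-covariance: find the lag maximizing the
   leading singular value, refine it to sub-bin resolution by parabolic
   interpolation, take the singular vectors as loadings, deflate at all
   lags, repeat. This also resolves the latent-mixing ambiguity a
   simultaneous (zero-lag) SVD suffers from.
2. **Delay refinement.** After EM converges, each delay is pinned at the
   optimum of its profile marginal likelihood on a coarse-to-fine grid with
   other parameters fixed.

Delay significance uses the bootstrap: per resample (100 trials with
replacement), the fitted model's per-trial log-likelihoods are compared to
the same model with one latent's delay zeroed; the latent is significant if
fewer than 5% of resamples favor the zero-delay model. Because trials are
independent given parameters, resampling per-trial log-likelihood sums is
exact. The resample count (100) is config-exposed (unstated in the source).

# Directed predictivity

* **Transfer entropy**: plug-in estimator on binary 1 ms bins with
  single-bin source/target histories at delays 0..30 ms; the maximum over
  delays is reported. No bias correction is applied — the circular-shift
  null (300 shifts of ≥ 3 s) absorbs estimator bias. Movement epochs are
  segmented at quiescent-mean + 7 SD, with sub-100 ms gaps merged and
  sub-10 ms epochs dropped, and concatenated with zero pads longer than the
  maximum delay.
* **Granger causality**: logistic point-process regression of each target
  on 30 ms of ensemble history (30 one-ms indicator lags per unit — fixed
  so all statistics share one χ²₃₀ reference) plus a piecewise-constant
  exogenous trial-time modulation whose bin width (1/5/8/10/20/25 ms) is
  selected by AIC. Pairs are excluded on non-convergence or deviance below
  1e−8 ("perfect fit"); a post-hoc rule drops the low-rate, p > 0.95
  cluster with its rate cutoff exposed as config.
* **CCM**: shadow manifolds are built from the target's smoothed (σ = 10 ms)
  activity within each of 30 sampled trials, with E = 4, τ = 1, K = 5;
  manifold points require 500 ms of within-trial history. Cross-map skill is
  the correlation between actual source values and values predicted from
  manifold neighbors, maximized over delays 0..30 by 3 ms; permutations
  reuse the same neighbors and optimal delay, so the null costs almost
  nothing. A `stride` parameter thins manifold points for compute control.
* **False-null fraction**: one minus a Storey-type smoothed-spline estimate
  of π₀, with a Benjamini–Hochberg threshold helper for display at
  FDR 0.10.

Permutation p-values are reported both as the raw exceedance fraction and
in the smoothed form $(1+k)/(n+1)$, which never returns exactly zero and is
what the calibration tests check.

# The dual-population network

Two populations of 500 rate units (80% excitatory), within-region
connection probability 5%, across-region 0.1% from excitatory non-muscle
units only; 100 excitatory units per region form the trainable muscle
readout and a disjoint 100 the fixed-weight neural readout. Dynamics are
discrete-time leaky integration (1 ms step, 10 ms time constant,
rectified-linear transfer) — the simplest standard rate-network family,
since the source specifies none. Inputs are the go sigmoid (k = 0.3, ramp
start −40 ms) and, on inactivation trials, a light signal (rise k = 0.5 at
onset, plateau to +50 ms, fall k = 1 centered at the plateau end — the only
centering consistent with the printed "below 0.01 within 5 ms") routed to
the inactivated region's inhibitory units.

Training minimizes summed readout MSE over the three conditions (on
inactivation trials only the non-inactivated region's neural readout enters
the loss) by Adam with projection after every step (sign clipping for
Dale's law; structural zeros are never represented). The stated cap of
100,000 single-condition trials is realized as full-batch steps with early
stopping on a plateau or on normalized error below a target. The optional
symmetric penalty λ·|ΣW_{A→B} − ΣW_{B→A}| (default λ = 1 when enabled)
uses a subgradient. Training targets place the downstream suppression on
the *recorded* region's trace (strong on B under A-inactivation, weak on A
under B-inactivation) — that is the asymmetry the experiment measures and
the only one the loss can see.

# Known limitations

* The delayed-latent fitter is validated by self-consistency (parameter
  recovery on data from its own model class and from the spiking
  generator), not by numerical identity to the original implementation.
* At the generator's default SNR, individual across-latents capture only a
  few percent of single-trial binned variance; delay recovery to half-bin
  accuracy is demonstrated in a strong-sharing regime (~15–20 spikes/s
  latent modulation against ~20 spikes/s baselines). Weak-latent delay
  estimates degrade gracefully but are not certified.
* CCM on stochastic spiking data detects coupling in both directions
  (expected for noisy unidirectional drivers); strict directionality is
  certified on the deterministic coupled-map benchmark, and direction on
  spiking data is asserted as an ordering of skills.
* Network instances are trained for hundreds (not tens of thousands) of
  steps; fits reach normalized error < 0.1, and the emergent asymmetry
  ordering is reproduced, but the magnitude of the simulated downstream
  effect remains smaller than the target's.
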
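---
title: "Latent spiking states and brain state: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent spiking states and brain state: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spikestate` models spontaneous cortical population spiking as a discrete
latent process and relates the inferred "spiking states" to classical
brain-state observables: the local field potential (LFP), trial-by-trial
variability of sensory-evoked responses, and whisking behavior.  This
vignette describes the models, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer would want to know about.  It states no
empirical result that the package's test suite and acceptance script do
not themselves compute.

## The Poisson-emission hidden Markov model

Spike counts are binned at $\Delta = 40$ ms, matching the 25-Hz frame
rate of whisking videography.  At each bin the population occupies one of
$N_S$ latent states following a first-order Markov chain with transition
matrix $A_{ij} = P(s_{t+\Delta} = j \mid s_t = i)$.  Given the state,
spike counts are Poisson and conditionally independent across neurons:

$$P(\{y_n\} \mid s) \;=\; \prod_{n=1}^{N_C}
  \frac{(\lambda_n(s)\Delta)^{y_n} e^{-\lambda_n(s)\Delta}}{y_n!}.$$

Rates $\lambda_n(s)$ are stored in spikes/second and converted by
$\Delta$ at the emission; `rates_per_bin()` exposes the spikes-per-bin
view used in rate-pattern displays.

**Inference.** `forward_backward()` computes $P(s_t \mid y_{1:T})$ with
per-bin rescaling, so segments of arbitrary length cannot underflow.
Recording segments are independent chains sharing parameters; fresh
segments start from the stationary distribution of $A$ (the leading left
eigenvector), which matches long-recording statistics.

**Estimation.** `fit_em()` is Baum–Welch EM.  The M-step for the rates is
$\hat\lambda_n(i) = \sum_t \gamma_t(i) y_n(t) / (\Delta \sum_t
\gamma_t(i))$ with a floor of $10^{-3}$ spikes/s, which prevents
$\log 0$ when a state captures a silent neuron.  During fitting the
initial state distribution of each segment is held fixed at uniform
rather than tied to the stationary distribution of the current $A$:
EM over $(A, \lambda)$ with a fixed parameter is provably monotone in
the training likelihood, whereas tying the initial distribution to $A$
breaks that guarantee for a contribution that is $O(\text{segments})$
against $O(\text{bins})$.  Downstream inference uses the stationary
distribution, as intended for long recordings.  Initialization
partitions bins into $N_S$ quantile groups of the population count
(a k-means-style split by overall activity) and jitters the implied
rates per restart; 5 restarts by default, best training likelihood
wins.  Convergence is a relative change below $10^{-6}$ or 500
iterations; hitting the cap returns the best fit with a warning flag.

**State overlap.** For two states the Bhattacharyya distance per neuron
is $D_n = \tfrac12(\sqrt{\lambda_a\Delta} - \sqrt{\lambda_b\Delta})^2$;
distances add across neurons by conditional independence and
$BC = \exp(-\sum_n D_n) \in [0, 1]$.  The closed form is verified in the
tests against a truncated-sum overlap oracle on random rate pairs.

**Ties.** MAP states break posterior ties to the lowest state index,
everywhere (per-bin decoding and pre-stimulus assignment).

## Model-quality controls

Recordings are split by alternating segments (1st, 3rd, 5th… train;
2nd, 4th, 6th… test).  `likelihood_curve()` reports, per model size, the
normalized test log-likelihood (total over segments divided by
$T \times N_C$), the gain over the one-state model, a *simulation
ceiling* (likelihood of fresh data generated from the fitted model at
matched length, mean ± SD over repetitions), and a *full-shuffle floor*
(each neuron's counts independently permuted in time, which preserves
marginals but destroys temporal and cross-neuron structure).  On
synthetic data the expected ordering is shuffle ≤ data ≤ ceiling within
noise; note that the ceiling is an idealization, not a bound — a
slightly blurred fit has higher entropy than the truth, and its own
samples can be marginally harder to predict than real data, which is
why the package (like the acceptance tests) allows a 2-SD margin.

`single_neuron_shuffle_loss()` permutes one neuron's counts in time
(across the whole evaluation set by default; a within-segment option
exists) and reports the drop in normalized log-likelihood — a measure of
how strongly that neuron's timing is coupled to the population state.
`rate_cv()` is the population-SD/mean of $\lambda_n(\cdot)$ across
states; the n-denominator convention is documented because the source
convention is not stated anywhere.  Group contrasts (FS vs RS) across
recordings use a two-level `hierarchical_bootstrap()` (recordings with
replacement, then neurons within recording with replacement), statistic
mean(FS) − mean(RS); the one-sided p is the bootstrap mass at or below
zero (direction FS > RS, the direction of interest), with a two-sided p
and z = mean/SD of the bootstrap distribution also reported.  Resamples
that lose a group entirely are redrawn.

## The LFP state metric

`lf_hf_ratio()` computes, per non-overlapping 1-s window, the ratio of
average Fourier amplitude in 1–10 Hz (LF) to 30–90 Hz excluding the
58–62 Hz line-noise region (HF), both bands edge-inclusive.  A
rectangular window is the default since the source convention specifies
only "spectrogram at 1-s intervals"; a Hann taper is available.  The
state metric is $r = \log_{10}(\mathrm{LF/HF}) - 1$ and the labels are
L (synchronized, ratio > 10) versus H (activated, ratio ≤ 10); the
boundary $r = 0$ maps to H.  A zero HF amplitude (degenerate synthetic
input) yields ratio $\infty$, label L, with a warning.

Spiking bins are assigned to the 1-s window containing their left edge.
`order_states_by_lfp()` ranks states by the Laplace-smoothed occupancy
ratio $P(H\mid s)/P(L\mid s)$ (+1 count per cell avoids division by
zero), H-affine first, ties by state index, never-observed states last
with a flag.  `transition_graph()` exports off-diagonal transitions
strictly above 0.05 for display.

## Decoding LFP state from spiking

One 40-ms bin per second (the bin whose left edge lies on the second) is
sampled and labeled with its window's H/L state; the majority class is
subsampled so chance is exactly 50%.  Feature families: summed
population count, population count vector, inferred state
representation, and single-neuron count.  State features default to the
posterior probability vector — strictly more information than a one-hot
MAP encoding and degrades gracefully — with the one-hot mode kept for
literal replication.  The classifier is a linear max-margin model:
L2-regularized squared-hinge loss (the differentiable member of the
family, and the default loss of the standard linear-SVM solvers), fit by
BFGS on internally standardized features with $C = 1$; no linear-SVM
package exists in the target environment, so the solver is implemented
in-package.  Stratified 5-fold cross-validation with a fixed seed
reports mean ± SD accuracy.

## State-dependent evoked responses

The evoked count of a trial and neuron is the spike count in the
post-stimulus window (5–25 ms) minus the pre-stimulus window (−20–0 ms).
Trials are assigned a pre-stimulus state by decoding the pre-stimulus
raster and taking the most probable state in the final bin (−40–0 ms).
The decoding window defaults to the full 1 s of pre-stimulus activity;
a shorter window (e.g. 12 bins ≈ 500 ms) is configurable because the
source material describes both, and the final-bin rule makes the two
nearly identical in practice.

`state_dependence_test()` builds the null by permuting the state labels
over trials — preserving per-state trial counts exactly, equivalent to
re-drawing matched assignments — 200 times, and scores each neuron ×
state pair by the percentile of its empirical mean among the shuffle
means, with half-weight for ties (which matters on count data at 200
shuffles).  Labels follow the two-tailed 1% criterion: facilitated above
the 99.5th percentile, suppressed below the 0.5th.  With a continuous
statistic the expected flag rate is $2/201 \approx 0.995\%$; on low-rate
neurons, exactly tied shuffle means cannot reach the extremes, so the
empirical rate on realistic synthetic worlds sits slightly below 1%
(the acceptance script measures it at a few thousandths under the
binomial tolerance of the criterion).  `trial_shuffle_control()`
permutes the labels once before re-running the test, giving the
empirical false-positive baseline with matched trial counts.
`summarize_by_lfp_affinity()` relates detected states to their L:H
occupancy ratios (facilitated states are expected L-affine, suppressed
H-affine, in worlds wired that way).

## Whisking

Onsets require 400 ms of quiescence (≥ 9 of the 10 preceding 25-Hz
frames below a fixed per-recording threshold) followed by at least two
supra-threshold frames, at least 500 ms from segment edges.  The onset
frame must itself be the first supra-threshold frame of its bout
(its predecessor below threshold): without this transition requirement
the literal 9-of-10 rule would also flag the second frame of every long
bout.  The default threshold is the midpoint of a two-component split
(2-means) of the energy distribution, emulating the per-recording fixed
threshold chosen by eye; it is configurable.

Whisking energy is discretized into four equipartition bins (empirical
quartiles, stable-rank tie-breaking, occupancies equal within one
frame; invariant under monotone transforms of the energy).  Mutual
information between label series is the plug-in estimator in bits per
40-ms bin, with an error bar from 50 half-data resamples and the
Miller–Madow first-order bias bound $(|X|-1)(|Y|-1)/(2N\ln 2)$ reported
for interpretation (no bias correction is applied, matching the plug-in
convention).  `compare_whisk_information()` aligns the 1-Hz LFP label to
bins by repeating it across the 25 bins of its second and compares
MI(whisk; states) with MI(whisk; LFP) on identical samples.

## The synthetic ground-truth world

`ground_truth_config()` states the world once; the generator's defaults
are the conditions the analyses assume, chosen as follows and not
revisited:

* **States and groups.** 7 states, 3 labeled H-affine and 4 L-affine
  (matching the observed split of states by LFP affinity).  Each row of
  $A$ keeps $1 - \text{cross\_group\_rate}$ of its mass within the row's
  group (default cross mass 0.02, i.e. group dwell ≈ 2 s), most of it on
  the diagonal (state dwell ≈ 400 ms), with Dirichlet-weighted
  off-diagonal spread so matrices vary across seeds.  Setting the cross
  rate to 0 gives an exactly block-diagonal matrix.
* **Rates.** 30 neurons, 8 FS.  RS base rates are log-normal with median
  1 spike/s (a realistic S1 RS figure); FS rates are scaled by 4 —
  consistent with the visibly higher FS rate bars in awake S1
  recordings — and FS across-state log-dispersion is doubled
  (`fs_cv_scale = 2`), which is what makes FS neurons carry more
  state information, as the cell-type contrasts assume.  A mild
  population-wide per-state multiplier (log-SD 0.3) creates overall
  rate differences between states.  The exact generative law is this
  package's choice; only the qualitative FS/RS contrasts are inherited.
* **LFP.** The surrogate is generated at the metric level: one
  $\log_{10}$ LF/HF value per second, mean 1.5 for L-majority seconds
  and 0.5 for H-majority seconds (±0.5 around the threshold at 1),
  Gaussian noise SD 0.2 — strong but imperfect coupling, ~1%
  misclassification at the default.  The source material does not state
  a generative model for the LFP given spiking state, so this coupling
  strength is a free parameter of the world, not an estimate.  A
  raw-signal mode (band-limited sinusoids + noise at 2 kHz) exercises
  the spectral pipeline.
* **Whisking.** Frame $k$ covers bin $k$ exactly (both 40 ms).  Energy
  fluctuates log-normally (SD 0.3) around a bout level of 1.0 while the
  state is in `whisk_states` (default states 1–2, H-affine — whisking
  accompanies the activated LFP state) and a base level of 0.1
  otherwise.
* **Evoked trials.** Each trial draws its true state from the
  stationary distribution, simulates the 1-s pre-stimulus raster
  backward through the time-reversed chain (exact under stationarity),
  and draws window counts Poisson with rate $\lambda_n(s)$ (pre) and
  $\lambda_n(s)(1 + g_s)$ (post).  Window counts are drawn
  independently of the binned raster given the state; physically the
  −20–0 ms window overlaps the final bin, and a thinning construction
  would correlate the two, but the independent draw keeps null
  calibration of the shuffle test a property of the test rather than of
  a decoding-feedback artifact.  With a constant gain $g$ across
  states the mean evoked count is $g\,\lambda_n(s)\,(20\,\mathrm{ms})$,
  which still depends on the state through $\lambda$ unless $g = 0$;
  zero gain is therefore the state-independent null.

**What the generator does not emulate** — and hence what a green test
does not establish: refractoriness and spike-history effects,
non-Poisson dispersion, gradual (non-Markov) state drift, layer
structure, electrode artifacts, or any feedback from behavior to
states.  Tests on this world validate the estimators and their
calibration, not the biological fidelity of the model class.

## Numerical choices and degenerate inputs

* Forward-backward uses per-bin rescaling plus a per-row shift of the
  emission log-probabilities; `gamma` rows are renormalized against
  floating-point drift.
* The rate floor ($10^{-3}$ spikes/s) bounds emission log-probabilities;
  EM transition rows that lose all mass (never-visited states) reset to
  uniform to keep the chain irreducible.
* `stationary_dist()` takes the leading left eigenvector and falls back
  to power iteration if the eigendecomposition is numerically unusable.
* Percentile ties in the shuffle test carry half-weight; exact-zero
  cases (constant series, empty states) are returned flagged rather
  than dropped silently.
* Equal-count ties in equipartition binning break by first occurrence
  (stable ranks), so occupancies stay within ±1 even with heavy ties.
* Seeds: every stochastic entry point takes a `seed` and restores the
  caller's RNG state; `run_pipeline()` fans a master seed out to stage
  seeds deterministically, so two runs with the same configuration are
  byte-identical.

## Known limitations

* The EM initializer partitions on the population count, so two states
  with identical total rate but different patterns may need several
  restarts to separate at small $T$.
* The simulation ceiling is estimated from a handful of repetitions;
  its SD at small test sets is itself noisy (hence the 2-SD margin).
* The squared-hinge solver is adequate for the small, standardized
  problems in this pipeline; it is not a general-purpose SVM.
* Plug-in MI is biased upward at small samples; the reported bound is a
  guide, not a correction.
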
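---
title: "Models and methods: CDA extraction and working-memory modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CDA extraction and working-memory modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cdawm)
```

`cdawm` implements the computational chain of a lateralized visual-working-memory
(VWM) EEG experiment: behavioural capacity estimation for delayed recognition,
mixture-model and target-confusability-competition (TCC) modelling of delayed-
estimation responses, and an ERP pipeline that derives the contralateral delay
activity (CDA). Because raw human data for this class of experiment is rarely
shareable, the package ships a synthetic-data generator that reproduces the
statistical structure every estimator assumes, with full ground-truth
bookkeeping. All empirical statements below are properties the test suite and
`scripts/acceptance.R` compute; nothing is quoted from any particular dataset.

## The experimental structure being emulated

A trial presents a spatial cue (200 ms), a jittered cue–stimulus interval
(400–600 ms in 50 ms steps), a bilateral sample array (750 ms) with one, three
or five items per hemifield, an unfilled delay (900 ms), and a probe. Memory
sets are either *homogeneous* (all items from one stimulus category —
orientation) or *heterogeneous* (one item per category: orientation, colour,
luminance). Homogeneity raises the demand on *context binding* — linking each
item to its trial-unique location — because identical-category items can only
be distinguished by where they appeared. The scientific question the pipeline
is built around is whether the CDA, the sustained contralateral-minus-
ipsilateral voltage during the delay, is sensitive to this binding demand or
only to the number of items retained.

All response domains are mapped onto a common 180-unit circular space;
nonmatch probes sit 90 units from the probed item, the maximal distance.

## Behavioural capacity: Cowan's k

For delayed recognition with single probes, capacity is estimated as

$$k = N \cdot (\mathrm{hit} - \mathrm{fa})$$

where $N$ is the set size, the hit rate is the proportion of correct
*nonmatch* responses and the false-alarm rate the proportion of incorrect
(*nonmatch*) responses on match trials. Under the generator's slot-style
response model — the probed item is in memory with probability
$\min(k/N, 1)$, otherwise the subject guesses "match" with a fixed rate —
the estimator is unbiased for the generating capacity regardless of the
guess rate, which is why `recognition_summary()` recovers the configured
`capacity_k` to Monte-Carlo precision. Timeout trials are excluded; negative
k is reported as computed, not clipped. When comparing homogeneity
conditions, heterogeneous cells are restricted to orientation probes by
default so that the probes being scored are physically identical across
conditions.

## The mixture model of delayed estimation

Recall errors in the 180-unit space are modelled as a mixture of target
recall, nontarget ("swap") responses, and uniform guessing:

$$p(\hat\theta) = p_T \,\phi_\kappa(2\Delta_t) +
  \frac{p_N}{m}\sum_{j=1}^{m} \phi_\kappa(2\Delta_j) + \frac{p_U}{360}$$

with $\Delta_t$, $\Delta_j$ the signed circular errors to the target and to
nontarget $j$, and $\phi_\kappa$ a von Mises density. Two conventions matter
and are fixed package-wide:

* **Doubled circle.** Orientation-like spaces spanning 180 units are doubled
  onto 360 degrees before von Mises evaluation and halved back for sampling.
  $\kappa$ therefore refers to the doubled circle; published precision
  values using other conventions are not directly comparable.
* **Per-degree densities.** All component densities are expressed per degree
  of the doubled (360-degree) space, so the uniform component is exactly
  $1/360$ and log-likelihoods are comparable across nested models.

Fitting is by maximum likelihood with the simplex constraint handled exactly:
mixture weights are optimized in softmax space and $\kappa$ in log space
(bounds $10^{-4} \le \kappa \le 10^4$), using L-BFGS-B from 20 starts (one
deterministic moment-based start, the rest randomized under the caller's
seed). Solutions with $\kappa$ at its upper bound are flagged as
non-converged rather than rejected: they arise for legitimate degenerate
inputs (for example, error-free responses). Trial types without nontargets
cannot express swap errors, so the 2-component model ($p_N = 0$) is used
there; the 3-component model is reserved for 3-item homogeneous trials.
Large $\kappa$ never overflows because the Bessel normalization uses the
exponentially scaled `besselI`.

Group-level inference on the per-subject $p_N$ estimates runs both a
one-sample t test and a Wilcoxon signed-rank test against zero; a
Shapiro–Wilk check decides which is the headline (recovery distributions of
$p_N$ are typically right-skewed, in which case the Wilcoxon is reported).

## The TCC model

The TCC model treats recall as a max-signal race across $m = 180$ response
channels (the resolution of the response wheels). Channel $x$ carries
familiarity $d' f(\Delta_{x,t})$ plus independent unit-variance Gaussian
noise, where $f$ is the *psychophysical similarity function* measured with
Likert judgements and normalized as $f(x) = (S_x - S_{min})/(S_{max} -
S_{min})$ with $S_{min} = 1$, $S_{max} = 7$. The response probability of
channel $x$ is

$$P(x \mid t) = \int \varphi(z - d' f_x) \prod_{y \ne x} \Phi(z - d' f_y)\, dz,$$

evaluated with a 401-point trapezoid rule over $z \in [-8, 8 + d']$. The
integrand is smooth and decays to zero at both limits, so the trapezoid rule
converges super-algebraically here; the quadrature sum is validated against
1 within $10^{-6}$ on every call, and the pmf is cross-checked in the tests
against a $5 \times 10^6$-draw Monte-Carlo simulation of the max rule
(agreement within $2 \times 10^{-3}$ per channel, the Monte-Carlo
resolution). Similarity is measured at each domain's printed offset grid,
linearly interpolated between samples, and — where the response space
extends beyond the sampled range — linearly extrapolated from the last
segment and clamped to $[0, 1]$; channel distances (0–90 units) are rescaled
onto the sampled offset range so the three domains are treated uniformly.

`fit_tcc()` maximizes the summed log channel probability over $d' \in [0,
6]$ by golden-section search (deterministic); `fit_tcc_plus()` adds the swap
mixture

$$P(x) = (1 - p_{swap}) P(x \mid t) + p_{swap}\,\tfrac1m \textstyle\sum_j P(x \mid nt_j)$$

and optimizes $(d', p_{swap})$ jointly from a small deterministic grid of
starts. When the nontargets coincide with the target the swap rate is
structurally unidentifiable and the fit is flagged. The independent-noise,
single-$d'$ variant implemented here is the simplest published form of the
model; correlated-noise channel models are deliberately out of scope.

## The ERP pipeline

Epochs span $-1.5$ to $+2.5$ s around sample onset. The pipeline applies,
in order:

1. **Baseline correction** — subtract the mean of the 200 ms prestimulus
   interval per trial and channel. (The jittered cue–stimulus interval lies
   entirely before this window because epochs are sample-locked.)
2. **Amplitude rejection** — discard trials where any channel strictly
   exceeds 100 µV in absolute value (blink-scale artifacts).
3. **HEOG step rejection** — a split-half sliding window (200 ms window,
   20 ms step) flags a trial when the mean of the second half-window minus
   the first strictly exceeds 20 µV in absolute value: the signature of a
   lateral saccade, which would corrupt lateralized measures. With Gaussian
   noise of sd 5 µV the false-alarm rate is far below 5% while noiseless
   30 µV steps are always caught; 15 µV steps are never flagged (all
   threshold comparisons are strict, and the half-window means of a clean
   step reach at most 24/25 of its height at the implemented 20 ms step
   alignment).
4. **Subject exclusion** — a subject is dropped when any trial type retains
   fewer than 75 epochs.
5. **Lateralization** — left- and right-hemisphere posterior cluster
   averages are assigned per trial as contralateral or ipsilateral to the
   cued side; midline channels never contribute. Averaging across trials
   within subject × condition × load, then subtracting ipsi from contra,
   yields the difference wave whose delay-window mean is the CDA.
6. **Window means** — sample window $(0.200, 0.700)$ s and delay window
   $(0.950, 1.600)$ s after sample onset. These are derived from the event
   times: the delay window runs from 200 ms after sample offset (0.750 s)
   to 50 ms before probe onset (1.650 s); the sample window is the 500 ms
   interval beginning 200 ms after sample onset. Windows are half-open
   (`start <= t < stop`).

Band-pass filtering (0.1–30 Hz zero-phase Butterworth) and integer-factor
downsampling are provided but off the default path because the generator
already produces band-limited data at the 250 Hz analysis rate. Bad-channel
interpolation is a validated no-op hook: spherical-spline interpolation
needs real electrode geometry, which synthetic data does not have.
Independent-component-based ocular cleanup is likewise out of scope; the
amplitude and HEOG detectors are the artifact path, and the generator's
artifacts (step saccades, high-amplitude blink transients) are built to be
detectable by exactly these operators.

## The synthetic generator and its defaults

The generator's defaults describe a mid-sized study of this design:
28 subjects and 180 trials per subject × condition × load cell, matching
typical enrolled samples and per-load trial counts for CDA experiments of
this kind. Other defaults, chosen once as field-plausible values (no
published noise or effect calibration exists for this design):

* **Capacity** — mean 2.2 items (homogeneous) vs 2.8 (heterogeneous),
  between-subject sd 0.4: capacities near the classic 2–3 item range, with
  a heterogeneity advantage at supracapacity loads.
* **Mixture truth** — $p_T = 0.7$, $p_N = 0.15$, $p_U = 0.15$,
  $\kappa = 12$ for 3-item homogeneous trials; trial types without
  nontargets fold the swap mass into target/guess by renormalization.
* **CDA amplitudes** — $-0.9$, $-1.8$, $-1.8$ µV for loads 1, 3, 5: a
  1 µV-order component whose magnitude saturates beyond capacity. The
  constructor enforces saturation (magnitude may not grow between loads
  that both exceed capacity).
* **Bilateral homogeneity component** — $-1.0$ µV added to *both*
  hemispheres on homogeneous trials. This is the generative core of the
  package's headline qualitative check: a bilateral component shifts contra
  and ipsi delay means equally and must cancel in the contra − ipsi
  subtraction.
* **Noise** — 10 µV per-sample sd, 60% pink (1/f, spectrally shaped white
  noise computed by FFT) and 40% white: a realistic single-trial EEG noise
  scale with a realistic spectrum, without committing to any specific
  recording setup.
* **Artifacts** — 5% of trials receive a ±40 µV HEOG step held to the epoch
  end (a saccade, as seen by a step detector); 5% receive a >150 µV
  cosine-squared blink transient (width 300 ms) on frontal channels.
* **RT** — lognormal with small load and condition shifts; purely
  descriptive plumbing, as no generative RT model is claimed.
* **Likert ratings** — `round(1 + 6 exp(-offset / 20°) + N(0, 0.5))`
  clipped to 1–7, offsets expressed in the common scale where each domain's
  maximum offset maps to 90 units: anchored at 7 for identical pairs and 1
  at maximal dissimilarity, with an exponential-decay similarity shape of
  the kind measured psychophysically.
* **Luminance** is generated and scored circularly like the other domains
  (uniform treatment of the three 180-unit response spaces); a linear
  (reflecting) scoring flag exists but is off by default.

What the generator does **not** emulate: volume conduction and electrode
geometry (no forward model), ocular ICA topographies, autocorrelated
behavioural dynamics (learning, fatigue), or any coupling between the EEG
and behavioural layers beyond the shared design variables. Passing tests
therefore validate the *estimators and pipeline* under the stated
statistical structure — they are not evidence about any particular human
dataset.

## Numerical choices and degenerate inputs

* von Mises sampling uses the Best–Fisher rejection algorithm; densities
  use `besselI(..., expon.scaled = TRUE)`, so $\kappa$ up to the $10^4$
  bound is exact and finite.
* The likelihood floor `pmax(dens, 1e-300)` keeps the optimizer finite on
  boundary parameter vectors; fitted densities are never at the floor at
  the optimum.
* `rm_anova()` requires a fully crossed, balanced design with one value per
  subject × cell and refuses to impute. Degrees of freedom are computed
  from the design and reported uncorrected by default; Greenhouse–Geisser
  correction (contrast-projection epsilon) is available behind `gg = TRUE`.
  This matches the common reporting convention of uncorrected df.
* `paired_t()` flags zero-variance differences and returns $t = 0, p = 1$
  (identical inputs) or signed infinity (constant nonzero shift) rather
  than erroring.
* Pink noise is synthesized at the next power-of-two length and truncated,
  with an analytic (Parseval) normalization to unit variance.
* Ties in the response wheel are impossible by construction (continuous
  responses are binned to 180 channels by rounding; `%% m` closes the
  wrap).

## Problem sizes used by the checks

The test suite and acceptance script size their simulations to the study's
stated conditions: 20 replicate datasets of 1,500 trials for mixture
recovery, 2,000-trial datasets (20 replicates) for TCC recovery, a
$5\times10^6$-draw Monte-Carlo oracle for the response pmf, 1,000 trials per
condition for the HEOG detector rates, 200 trials per cell at 20 µV noise
for CDA injection recovery, the full 28-subject default study for the
end-to-end dissociation, and 2,000 null replicates for ANOVA type-I
calibration.

## Known limitations

* The Exp-style electrode cluster is configurable but defaults to a single
  parieto-occipital set per hemisphere; no claim is made about optimal
  cluster choice.
* $\kappa$ is only interpretable under the doubled-circle convention stated
  above.
* The TCC-plus swap mixture is one published formalization of swap errors
  within TCC; variants that mix at the familiarity level rather than the
  pmf level exist and would require a different likelihood.
* `exclude_low_trial_subjects()` applies the fixed 75-trial rule; for
  designs with far fewer trials per cell the threshold must be set by the
  caller, as `run_study()` exposes via `min_trials`.
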
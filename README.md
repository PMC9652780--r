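# cdawm

Tools for the computational chain of lateralized visual-working-memory (VWM)
EEG experiments, for cognitive neuroscientists who analyse delayed
recognition, delayed estimation ("continuous report") and the contralateral
delay activity (CDA).

The package covers four linked analyses:

* **Behavioural capacity** for change detection, Cowan's
  `k = N · (hit − fa)`, per subject × condition × set size, with
  orientation-probe filtering for homogeneity comparisons.
* **Mixture modelling** of recall errors on the 180° circular stimulus
  space: maximum-likelihood estimation of target recall `pT`, swap rate
  `pN`, guess rate `pU` and von Mises precision `κ` (doubled-circle
  convention), with per-trial density
  `pT·VM(2Δt; κ) + (pN/m)·Σj VM(2Δj; κ) + pU/360`.
* **TCC modelling**: psychophysical similarity functions estimated from
  Likert data (`f = (S − 1)/6`), the max-signal-rule response pmf
  `P(x|t) = ∫ φ(z − d′f_x) Π_{y≠x} Φ(z − d′f_y) dz` over 180 response
  channels, and maximum-likelihood `d′` (plus a swap rate `pSwap` in the
  TCC-plus variant for trials with nontargets).
* **ERP pipeline**: baseline correction, 100 µV amplitude rejection,
  split-half sliding-window HEOG saccade rejection (200 ms window / 20 ms
  step / 20 µV), low-trial subject exclusion (<75 epochs per trial type),
  contralateral/ipsilateral posterior-cluster averaging, difference waves,
  and sample (0.20–0.70 s) and delay (0.95–1.60 s) window means — the
  delay-window difference being the CDA.

A synthetic-data generator (`gen_config()`, `gen_recognition_trials()`,
`gen_recall_trials()`, `gen_likert_trials()`, `gen_eeg_epochs()`) emulates
the full study — capacity-limited recognition behaviour, mixture-generated
recall, monotone Likert similarity, and epoched EEG with a load-saturating
contralateral component, an optional bilateral homogeneity component, 1/f +
white noise, step saccades and blink transients — with ground truth stored
for every trial, so each estimator is testable by parameter recovery.

## Worked example

Fit the three-component mixture model to synthetic 3-item recall data whose
generating parameters are known:

```r
library(cdawm)

cfg <- gen_config(seed = 7, n_subjects = 1, trials_per_cell = 1500,
                  mixture_truth = list(pT = 0.7, pN = 0.15, pU = 0.15, kappa = 12))
trials <- gen_recall_trials(cfg, trial_types = "3O")
fit_mixture(trials, n_components = 3, restarts = 20, seed = 1)
#> <mixture_fit> 3-component, n = 1500 trials
#>   pT = 0.695  pN = 0.158  pU = 0.148  kappa = 12.64
#>   logLik = -7652.86  converged = TRUE (20/20 restarts usable)
```

The fit recovers the generating weights to within sampling error: about 70%
of responses are target recalls with precision κ ≈ 12 on the doubled
circle, 15–16% are swaps to a nontarget, and the rest are uniform guesses.

Running the complete study — simulation, preprocessing, CDA extraction,
model fits and factorial statistics — takes a few minutes:

```r
study <- run_study(gen_config(seed = 11))
study
#> <cdawm_study>
#>   28 subjects simulated, 0 excluded from ERP analyses
#>   Cowan's k ANOVA (condition x load):
#>          effect df_num df_den         F            p
#>       condition      1     27  30.92738 6.772056e-06
#>            load      2     54 271.45216 6.686579e-29
#>  condition:load      2     54  14.71724 7.912292e-06
#>   CDA ANOVA (condition x load):
#>          effect df_num df_den           F            p
#>       condition      1     27   0.3075282 5.837658e-01
#>            load      2     54 182.0076325 1.005643e-24
#>  condition:load      2     54   0.3044709 7.387712e-01
#>   homogeneity effect (homo - hetero, delay window): contra -0.993, ipsi -1.027, CDA 0.033 uV
#>   swap test (pN > 0): headline t, p = 4.748e-18
#>   qualitative pattern reproduced: TRUE
```

The report shows the dissociation the pipeline is built to expose: the
homogeneity manipulation shifts the raw delay-period signal by about −1 µV
at *both* contralateral and ipsilateral electrodes (a bilateral, set-wide
effect), so it cancels in the contra − ipsi subtraction — the CDA shows no
homogeneity effect (p = 0.58, residual 0.03 µV) while remaining strongly
load-sensitive. Cowan's k meanwhile is higher for heterogeneous sets at
supracapacity loads (the condition × load interaction).

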
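---
title: "Choosing a frame schedule for dynamic choline PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a frame schedule for dynamic choline PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinbin)
```

## Why frame binning matters

A dynamic PET acquisition records list-mode events that must be binned
into time frames before reconstruction. For a tracer with fast arterial
kinetics like ¹⁸F-fluoromethylcholine, the binning is a genuine design
trade-off: frames short enough to resolve the arterial peak are
count-starved, frames long enough to be quiet under-sample the input
function and bias the influx constant K1. `kinbin` quantifies that
trade-off by simulation so a 5-min dynamic protocol can be chosen before
patients are scanned.

## The kinetic model

The measured tumour concentration is modelled by the one-tissue
compartment model with a blood-volume term,

$$C(t) = V_B\,C_{\mathrm{IDIF}}(t) + (1 - V_B)\,K_1\, e^{-k_2 t} \otimes C_{\mathrm{IDIF}}(t),$$

with $K_1$ in mL/ccm/min (we treat ccm as mL of tissue, so the magnitudes
of $K_1$ and a pure rate coincide), $k_2$ in min⁻¹ and $V_B$ a unitless
fraction. Setting $k_2 = 0$ yields the irreversible 1T1K+VB variant with
one fewer free parameter. Internally all times are seconds and the rate
constants are divided by 60 at the model boundary; results are reported
per minute.

The convolution is advanced by an exact state-update recursion for the
exponential kernel: over one grid step $h$ the state decays by
$e^{-k_2 h}$ and accumulates the kernel-weighted integral of the input,
taken piecewise linear between samples. The scheme is unconditionally
stable and second-order accurate; the unit tests check it against the
closed form for an exponential input (relative error below $10^{-6}$ at
$h = 0.1$ s) and against a brute-force Riemann double sum.

## Time grids, frames and conventions

* Frames are contiguous half-open intervals $[t, t + \Delta t)$ starting
  at 0; a schedule string such as `"12x5,8x30"` expands to twelve 5-s
  frames followed by eight 30-s frames, 300 s in all.
* A framed value is the time-average of the fine-grid curve over the
  frame; framed curves are time-stamped at the frame midpoint. The
  midpoint convention is our choice — fitting software differs and the
  alternative (frame start) is not standard for curves this fast.
* The default simulation grid is 0.1 s, finer than the 1-s grid an
  interpolated clinical input function lives on, so even 3-s frames are
  averaged from 30 samples.

## The synthetic input function

No analytic arterial curve accompanies the clinical cohort this package
emulates (clinically the input function is image-derived, averaged across
patients from the fastest schedule and interpolated to 1 s — that
construction is implemented in `mean_idif()`). The stand-in
`synthetic_idif()` is a standard arterial parameterization: zero before a
5-s arrival delay, linear rise to the peak 30 s later, then a
three-exponential washout (rates 0.08, 0.015 and 0.0008 s⁻¹ with weights
0.70/0.22/0.08) whose slowest term models recirculation. Defaults give a
peak of 60 kBq/mL inside the first minute and a 5-min tail at ~7% of the
peak — the shape a clinical FCH bolus shows. All downstream numbers that
depend on the true patient curve (the exact per-schedule means and the
validation p-values) are therefore reproducible only qualitatively;
structural quantities (frame counts, calibrated SDs, bias orderings,
bookkeeping) are reproduced exactly.

## Noise model

Per frame, `add_noise()` returns
$C + c\,(\mathrm{Poisson}(C) - C)/\sqrt{\Delta t}$: zero-mean with
variance $c^2 C/\Delta t$, so doubling a frame's duration halves its
noise variance — the counting-statistics trade-off in miniature. The
Poisson draw uses the frame value itself (a real-valued mean is valid),
and noisy values may go negative; that is preserved. The scale $c$ is not
identifiable from published summaries, so it is calibrated: the shipped
`scripts/calibrate_noise.R` finds, by secant iteration, the $c$ for which
the SD of fitted K1 at the reference `12x5,8x30` schedule over 1000
realizations is ≈0.014 mL/ccm/min under the default setup — the SD scale
clinical Monte Carlo tables report. The calibrated default is
$c = 0.47$. Noise is applied to frame-averaged values (the frame duration
appears in the formula), not to the fine-grid curve.

## Fitting and model selection

`fit_tac()` minimizes the unweighted residual sum of squares between the
framed data and the frame-averaged model prediction with
Levenberg–Marquardt (`minpack.lm::nls.lm`), bounds
$K_1 \in [0,5]$, $k_2 \in [0,5]$, $V_B \in [0,1]$, start
$(0.1, 0.1, 0.05)$, and stopping at a relative rss change of $10^{-8}$ or
500 iterations. Non-convergence is a flag, never an exception. Two
details matter:

* **Input-function handling** (`idif_mode`). With `"framed"` (the
  default for scheme comparison) the input function is rebinned to the
  data's own schedule and linearly interpolated back to the fine grid —
  emulating clinical extraction of the arterial curve from the same
  reconstruction. This is the mechanism that biases coarse schedules: a
  60-s first frame flattens the bolus peak. With `"fine"` the 0.1-s curve
  is used directly; then any schedule recovers noise-free truth to within
  optimizer precision, confirming that frame-averaging alone does not
  bias the estimate.
* **Multi-start.** Bounded LM can stall when $k_2$ collapses onto its
  zero bound from a poor start. `default_fit_starts()` provides five
  physiologically spread starts that reach the same optimum on noiseless
  default problems; for routine fits the single default start is
  sufficient and is what the Monte Carlo engine uses.

Model choice between 1T2k+VB and 1T1K+VB uses the small-sample criterion
$\mathrm{AICc} = n\ln(\mathrm{rss}/n) + 2k + 2k(k+1)/(n-k-1)$; exact ties
go to the model with fewer parameters. Which AICc variant clinical
software uses is unstated anywhere we know of; the least-squares form
above is our documented choice.

## Monte Carlo design

One fixed truth curve per study ($K_1 = 0.506$, $k_2 = 0.150$,
$V_B = 0.05$ by default — $V_B$ is never reported clinically and is a
configuration parameter), 1000 noise realizations per schedule,
realization $i$ seeded with `seed + i` so runs are reproducible and
schedule-order independent. Converged fits are summarized by mean, SD and
the normal-theory CI of the mean, $\bar K_1 \pm 1.96\,s/\sqrt{n}$ — the
formula consistent with published CI half-widths of
$\approx 1.96\,\mathrm{SD}/\sqrt{1000}$. Unconverged realizations are
excluded and counted; a schedule with under 50% convergence is flagged,
not dropped. Ranking is by $|\bar K_1 - K_1^{\mathrm{target}}|$ with SD
as tie-break. Pairwise Wilcoxon tests between schedules' realization K1
values are available as an optional descriptive output
(`scheme_pairwise_tests()`); whether the original analysis used ANOVA or
pairwise tests is unstated, so we do not promote either to an inference.

## The synthetic cohort

`sample_lesion_params()` draws lesions from truncated normals matching
the published summaries — $K_1 \sim N(0.506, 0.176^2)$ on
$[0.216, 1.246]$, $k_2 \sim N(0.150, 0.08^2)$ on $[0.008, 0.402]$ —
independently (the joint patient distribution is unknown), with
$V_B \sim U(0.01, 0.10)$. Draws use inverse-CDF sampling, so a seed fixes
the cohort exactly. Each lesion × schedule cell receives a single noise
realization, as in clinical data where each lesion is observed once per
reconstruction. The SUV-like static measure is computed from the
noiseless modelled 0–5 min curve; the clinical SUVmean comes from a
separate 10-min static image, so our proxy supports rank-correlation
checks (positivity, reproducibility) but not the clinical correlation
magnitude.

## Validation statistics

The paired Wilcoxon signed-rank test discards zero differences, midranks
ties, takes $\min(W^+, W^-)$ as the statistic, and enumerates all $2^n$
sign assignments exactly up to $n = 12$ (4096 assignments, instant);
beyond that it uses the normal approximation with midrank tie correction
and a 0.5 continuity correction, which agrees with the exact p to within
0.02 at the threshold. Spearman's $\rho$ is the Pearson correlation of
midranks with the t-approximation p-value. Both are implemented
in-package because their exact conventions (enumeration threshold,
tie and zero handling) are part of the pipeline's contract; the test
suite cross-checks them against `stats::wilcox.test` and
`stats::cor.test`. No multiple-testing correction is applied across the
six schedule comparisons, matching the clinical analysis; the validation
table reports raw p-values.

## Problem sizes and what the tests show

The unit suite exercises the pipeline at reduced sizes chosen for tight
feedback: 100 realizations for Monte Carlo structure checks, 200 for the
model-selection rates, $10^5$ draws for the noise moments. The acceptance
script runs the full design — 1000 realizations per schedule across the
seven blood-phase and five tissue-phase schedules, and the 37-lesion
cohort (259 fits). Passing tests demonstrate correctness of the
machinery and the qualitative bias mechanisms on the synthetic input
function; they cannot certify the clinical tables, which depend on the
unpublished patient-derived arterial curve, the unreported noise scale
and the unreported blood-volume fraction.

## Known limitations

* Reconstruction-correlated noise is not modelled; post-reconstruction
  PET noise is far from independent Poisson.
* No dispersion or delay term between artery and tissue beyond the
  global bolus re-origin.
* Two-tissue compartment models, partial-volume and metabolite
  corrections, and image-domain operations (VOI delineation, DICOM I/O)
  are out of scope.
* The K1–k2 correlation across lesions defaults to independence, which
  likely understates biological covariance.
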
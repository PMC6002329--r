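# kinbin

Frame-schedule optimization for dynamic ¹⁸F-fluoromethylcholine (FCH) PET
kinetic modelling.

## The problem

Modern PET systems acquire dynamic studies in list mode, but kinetic
analysis requires binning those events into time frames before
reconstruction — and there is no accepted standard for how. Short frames
resolve the arterial bolus but are count-starved and noisy; long frames
have good counting statistics but under-sample the input function and bias
the influx estimate. `kinbin` is a simulation toolkit for choosing the
frame schedule of a 5-min dynamic FCH study of prostate cancer, aimed at
physicists and kineticists designing dynamic protocols.

## The model

Tumour uptake follows the reversible one-tissue compartment model with a
blood-volume term (1T2k+VB):

    C(t) = VB · C_IDIF(t) + (1 − VB) · K1 · e^(−k2·t) ⊗ C_IDIF(t)

where `C_IDIF` is the arterial input function, `K1` (mL/ccm/min) the
blood-to-tissue transfer coefficient, `k2` (min⁻¹) the efflux constant and
`VB` the fractional blood volume; fixing `k2 = 0` gives the irreversible
1T1K+VB variant, and the two are compared with the small-sample Akaike
criterion `AICc = n ln(rss/n) + 2k + 2k(k+1)/(n−k−1)`.

Candidate schedules are evaluated by Monte Carlo: the modelled tumour
curve is rebinned into each schedule, perturbed with frame-duration-scaled
Poisson noise

    added noise = c · (Poisson(C) − C) / √dt

for 1000 realizations, refitted by Levenberg–Marquardt, and the schedules
ranked by the distance of the mean fitted K1 from the target value
(0.506 mL/ccm/min, the cohort-average influx). A synthetic lesion cohort
drawn from the published K1/k2 distributions feeds the clinical-validation
stage: paired Wilcoxon signed-rank tests of each schedule against the
optimal one, and the Spearman correlation of K1 with an SUV-like static
measure.

## Worked example

```r
library(kinbin)

idif  <- synthetic_idif()                              # arterial bolus, 0.1-s grid
truth <- kinetic_params(k1 = 0.506, k2 = 0.150, vb = 0.05)

# one noisy framed acquisition, fitted back
sch   <- parse_schedule("12x5,8x30")
tac   <- framed_prediction(idif, truth, sch)
noisy <- withr::with_seed(7, add_noise(tac, sch, noise_config(c = 0.47)))
fit_tac(noisy, idif, sch)
#> <tac_fit> 1T2k+VB on 12x5,8x30
#>   K1 = 0.5139 mL/ccm/min, k2 = 0.1599 /min, VB = 0.0395
#>   rss = 3.057 (n = 20, k = 3), AICc = -30.064, converged: TRUE

# Monte Carlo comparison of three schedules, ranked against the target K1
cfg <- study_config(
  schedules = list(parse_schedule("5x60"), parse_schedule("10x30"),
                   parse_schedule("12x5,8x30")),
  noise = noise_config(c = 0.47, seed = 1),
  n_realizations = 200
)
rank_schemes(run_scheme_comparison(cfg), target_k1 = 0.506)
#> # A tibble: 3 x 9
#>   schedule_id mean_k1  sd_k1 ci_lo ci_hi n_realizations n_converged low_convergence abs_bias
#> 1 10x30         0.508 0.0232 0.504 0.511            200         200 FALSE            0.00170
#> 2 12x5,8x30     0.502 0.0113 0.500 0.504            200         199 FALSE            0.00399
#> 3 5x60          0.438 0.0494 0.431 0.445            200         200 FALSE            0.0677
```

The single fit recovers the generating parameters to a few percent under
realistic noise. In the comparison table, the coarse `5x60` schedule is
biased low by ~0.07 mL/ccm/min — its 60-s first frame flattens the
arterial peak — while the schedules with a finely sampled blood phase sit
within half a percent of the truth; `12x5,8x30` has the smallest SD of the
unbiased schedules. `run_full_study()` chains all stages (blood phase,
tissue phase, synthetic cohort, validation statistics) and writes every
table as CSV with a provenance log.

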
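# paphantom

Dynamical modeling and characterization of photoacoustic (PA) signals from
tissue-mimicking polyvinyl-alcohol (PVA) hydrogel phantoms.

## What problem this solves

PVA hydrogels are standard phantoms for developing photoacoustic and
ultrasound imaging: their acoustic, optical and mechanical properties can be
tuned through the PVA concentration and molecular weight. A pulsed laser
heats the gel, thermoelastic expansion launches a pressure wave, and a
transducer records a damped oscillation. Characterizing a phantom panel means
extracting, from those ring-downs and a few auxiliary measurements, the
quantities that describe the material:

* **modal parameters** — the trace is modeled as the impulse response of a
  second-order linear system,
  `y(t) = G (ωn/√(1−ζ²)) e^(−ζωn t) sin(ωn√(1−ζ²) t)`;
  the damping ratio ζ (energy absorption) and natural frequency ωn (energy
  transfer) are recovered by **output-only N4SID subspace identification**: a
  block-Hankel arrangement of the samples, orthogonal projection of future
  onto past outputs, SVD truncation at the order chosen by the
  singular-value gap, and a least-squares solve for the state-space matrices
  {A, B, C}; ζ and ωn follow from the eigenvalues of A through
  `ωn = |ln λ|/ts`, `ζ = −cos(∠ ln λ)`. Fit quality is the NRMSE percentage.
* **time-domain descriptors** — peak-to-peak amplitude, acoustic arrival time
  t_a, and speed of sound `c = D/t_a` from the sample diameter.
* **optical coefficients** — integrating-sphere ratios `Rcd = m·Pr/Pd`,
  `Tcd = m·Pt/Pd`, `Tc = Pcoh/Po`, inverted to (µa, µs, g) through a
  Henyey–Greenstein Monte-Carlo slab model driven by Nelder–Mead; reduced
  scattering `µs′ = µs(1−g)`.
* **porosity and mechanics** — pore-diameter histograms on 0–80 µm decade
  bins with lognormal fits, plus ρ = m/V, E = σ/ε and the PVA recipe weight.

A synthetic panel generator reproduces the nine-hydrogel study design (five
MW1 concentrations, four MW2) with the reported concentration trends, so the
whole pipeline is testable end to end without access to the original
waveforms.

## Worked example

Generate the MW1 half of the synthetic panel, identify one trace, and fit the
concentration trend of the recovered damping ratios:

```r
library(paphantom)

pan <- generate_panel(panel_spec(mw = "MW1"), seed = 1)
fit <- n4sid_fit(pan$signals$MW1_07)
fit
#> N4SID identification: order 2, NRMSE = 97.72%
#>   leading singular values: 0.00145, 0.00105, 1.06e-05, 9.44e-06
#>   modal: f_n = 2.803 MHz, zeta = 0.2391

pa_features(pan$signals$MW1_07)
#> PA features (threshold arrival): t_a = 25.6 us, A_pp = 0.8929 mV, c = 1551 m/s

res <- identify_panel(pan, order = 2)
res[, c("sample_id", "concentration", "zeta_true", "zeta_est", "nrmse_percent")]
#>   sample_id concentration zeta_true  zeta_est nrmse_percent
#> 1    MW1_07             7      0.24 0.2390533      97.72002
#> 2    MW1_09             9      0.28 0.2806395      97.83432
#> 3    MW1_12            12      0.34 0.3426586      97.72609
#> 4    MW1_15            15      0.40 0.4033599      97.49358
#> 5    MW1_20            20      0.50 0.5059605      97.46844

fit_concentration_trend(res$concentration, res$zeta_est, degree = 1)
#> Degree-1 trend fit: R^2 = 1.0000
#>   coefficients (ascending powers): 0.0959175, 0.0205093
```

Reading the output: the SVD gap (two singular values two orders of magnitude
above the rest) selects a second-order model; the identified model reproduces
the noisy trace to 97.7% NRMSE at 20 dB SNR; ζ = 0.239 against a generating
value of 0.24; the arrival at 25.6 µs with the 39.70 mm diameter gives a
speed of sound of 1551 m/s; and across the panel the recovered damping ratios
rise linearly with concentration (slope 0.021 per percent, R² ≈ 1.00).

The model, the preprocessing choices (block-average decimation, tail-based DC
removal, arrival windowing) and the generator's assumptions are documented in
`vignettes/pa-dynamical-modeling.Rmd`.

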
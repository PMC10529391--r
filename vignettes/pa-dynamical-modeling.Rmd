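---
title: "Dynamical modeling of photoacoustic signals from hydrogel phantoms"
author: "paphantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical modeling of photoacoustic signals from hydrogel phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paphantom)
```

## The model

A pulsed laser heats an absorbing region of a tissue-mimicking PVA hydrogel;
thermoelastic expansion launches a pressure wave that an ultrasound transducer
records as a damped oscillation. Near the source, the pressure obeys a
second-order linear time-invariant equation of the mass-spring-damper form

$$\ddot p(t) + \tfrac{b}{m}\,\dot p(t) + \tfrac{k}{m}\, p(t) = \tfrac{u(t)}{m},$$

whose free parameters are the natural frequency $\omega_n$ ($k/m =
\omega_n^2$) and the damping ratio $\zeta$ ($b/m = 2\zeta\omega_n$). The
thermal-expansion, viscosity and Gruneisen factors of the underlying acoustic
physics enter only through these two ratios and an overall gain; they are not
separately identifiable from a single output trace, so the package never
represents them individually. The laser pulse (nanoseconds) is far shorter
than the acoustic period (microseconds), so the forcing is modeled as a unit
impulse at the acoustic arrival time and the recorded trace as the system's
impulse response

$$y(t) = G\,\frac{\omega_n}{\sqrt{1-\zeta^2}}\,
  e^{-\zeta\omega_n (t-\tau)}\,\sin\!\big(\omega_n\sqrt{1-\zeta^2}\,(t-\tau)\big),
  \qquad t \ge \tau,$$

valid in the underdamped regime $0 \le \zeta < 1$ that PA ring-downs occupy.
`simulate_pa_signal()` implements this closed form and refuses $\zeta \ge 1$
and sampling intervals with $\omega_n t_s \ge \pi$ (aliasing).

## Output-only N4SID identification

`n4sid_fit()` recovers a discrete-time state-space model $\{A, B, C\}$ from
one measured trace by numerical subspace identification:

1. the samples are arranged in past/future block Hankel matrices
   (`build_hankel()`);
2. the future outputs are projected orthogonally onto the row space of the
   past outputs (`orthogonal_project()`). No input signal is measured in a PA
   experiment, so past outputs serve as the instruments and the oblique
   projection along a future-input row space degenerates to this orthogonal
   projection; the oblique form remains available when an input is supplied;
3. the projection is factorized by SVD and truncated at the model order; the
   extended observability matrix is $\Gamma_i = U_1 S_1^{1/2}$, state
   sequences follow through pseudo-inverses, and a least-squares regression of
   the stacked states and outputs yields $A$ and $C$;
4. $B$ is estimated as the impulse-equivalent initial state: the linear
   least-squares minimizer of $\sum_k (y_k - C A^k x_0)^2$ over the fit
   window. Recovering $B$ from $\hat X_i$ through $A^{i-1}$ would be ill-posed
   because the modes decay.

The model order is chosen from the singular-value spectrum: the count of
leading values before the largest relative gap, among values at least
`threshold_ratio` (default $10^{-2}$) of the largest (`estimate_order()`). On
clean second-order data the third singular value collapses to rounding noise
and the rule returns 2; at 20 dB SNR the gap between the second and third
values still spans more than an order of magnitude.

Modal parameters come from the eigenvalues of $A$ through the principal
branch of the complex logarithm, $\omega_n = |\ln\lambda|/t_s$ and $\zeta =
-\cos(\angle\ln\lambda)$, taking the eigenvalue with positive imaginary part
(conjugates carry the same information). Fit quality is the NRMSE percentage,
$100\,(1 - \lVert y - \hat y\rVert/\lVert y - \bar y\rVert)$.

## Preprocessing choices

Oscilloscopes oversample PA ring-downs heavily (10 GS/s against a 2.25 MHz
transducer is ~4400 samples per period), which ill-conditions the Hankel
matrices. `preprocess_signal()` therefore decimates to a target of 30 samples
per dominant period (practical band 20-50). Two numerical decisions here
matter and deviate from the obvious defaults:

* **Decimation is a block average**, not a recursive (IIR) anti-alias filter.
  A finite moving average adds zeros but no poles, so the damped-sinusoid
  modal structure survives exactly ($\lambda^k \mapsto \lambda^{qk}$ up to a
  per-mode constant), while averaging $q$ samples cuts white-noise variance by
  exactly $q$. A Chebyshev decimator, by contrast, injects its own dynamics
  into the ring-down and inflates the apparent model order.
* **The DC offset is estimated from the last 10% of the record**, where the
  ring-down has decayed to the true baseline. Subtracting the full-record
  mean of a transient signal shifts its zero level and adds an artificial
  constant mode (a pole at 1).

Identification runs on the window from the detected acoustic arrival
(`arrival_time()`, default: first crossing of 10% of the global absolute
peak) to the end of the record. One decimated sample after the detected
arrival is dropped when decimation was applied, because a block straddling
the onset mixes baseline with ring-down. The Hankel block-row count defaults
to $i = 20$ but is capped at a tenth of the window length: for a heavily
damped ring-down ($\zeta = 0.5$) block rows lagged by two periods contain
essentially no signal at 20 dB, and spending samples on rows instead of
columns starves the regression.

All pseudo-inverses use an economy SVD with a relative cutoff of $10^{-12}$;
no matrix is explicitly inverted.

## Time-domain descriptors

`pa_features()` reports the peak-to-peak amplitude over the post-arrival
window, the arrival time, and the speed of sound $c = D/t_a$ (1 mm/µs = 1000
m/s) when the sample diameter is known. The arrival estimator is not uniquely
defined by the measurement protocol, so both a threshold method (default,
10% of peak) and a first-peak method are exposed and the method used is
recorded in the output.

## The synthetic panel generator

`panel_spec()`/`generate_panel()` emulate the nine-hydrogel study design: PVA
concentrations 7, 9, 12, 15, 20% for molecular-weight class MW1 and 7, 9, 12,
15% for MW2. The generator encodes the qualitative behavior reported for real
panels — damping ratio rising linearly with concentration, natural frequency
falling along a quadratic, amplitudes growing and arrivals lengthening with
concentration — with these defaults:

* $\zeta(c) = 0.10 + 0.02\,c$, spanning 0.24 to 0.50 across 7-20%;
* $f_n(c) = 3.0 - 0.004\,c^2$ MHz, spanning 2.80 down to 1.40 MHz (around
  the 2.25 MHz transducer band);
* arrival delays, outer diameters and peak-to-peak amplitudes equal to the
  published panel means (`hydrogel_panel_reference()`); the per-sample gain
  is solved in closed form so the noise-free peak-to-peak amplitude matches
  the published millivolt value exactly;
* additive white Gaussian noise at 20 dB SNR, defined against the RMS of the
  noise-free signal over its support (the study reports no noise model;
  white noise on the whole record is the plain instrument model);
* generation at 600 samples per oscillation period on a common 40 µs
  acquisition window. This emulates — scaled down for economy — the fixed,
  heavily oversampled oscilloscope window of the real experiment; the
  identification pipeline then decimates by ~20, which is what makes fit
  percentages above 95 attainable at 20 dB (block-averaging 20 samples
  raises the effective SNR by ~13 dB). Signals generated directly at the
  identification rate would cap the NRMSE of even a perfect model near 90.

What the generator does *not* emulate: transducer frequency response,
multi-path reverberation within the hydrogel walls, trigger jitter, and any
amplitude nonlinearity. Passing tests on this panel therefore demonstrate
that the pipeline recovers second-order dynamics and their concentration
trends under realistic sampling and noise — not that every real hydrogel
trace is second-order.

## Optics: sphere algebra and inverse Monte Carlo

`reflectance_cd()`, `transmittance_cd()` and `transmittance_coherent()`
implement the integrating-sphere ratios $R_{cd} = m P_r/P_d$, $T_{cd} = m
P_t/P_d$, $T_c = P_{coh}/P_o$ with wall coefficient $m = 0.98$ by default.
The forward model behind the inversion (`mc_forward_slab()`) is deliberately
minimal and documented as the package's own stand-in: a homogeneous,
index-matched slab with exponential free paths, absorption probability
$\mu_a/(\mu_a+\mu_s)$ per interaction and Henyey-Greenstein scattering. Its
coherent transmittance converges to the Beer-Lambert value
$e^{-(\mu_a+\mu_s)d}$ and its photon bookkeeping is exact by construction.
Sphere exchange corrections, specular ports and refractive mismatch are out
of scope (Fresnel boundaries could be added, but no refractive indices are
reported for these gels).

`invert_optical_props()` wraps a Nelder-Mead simplex around the forward
model (start $(0.5, 20, 0.7)$, at most 200 iterations, residual tolerance
$10^{-4}$, $10^5$ photons per evaluation). Two numerical choices keep the
inversion well behaved: parameters are optimized on transformed scales (log
for the coefficients, atanh for $g$) so bounds hold by construction, and
every forward evaluation reuses one seed (common random numbers), making the
objective deterministic and the simplex convergent despite Monte-Carlo noise.
With only two informative observables (panels whose coherent component is
negligible), three parameters are under-determined; `fix_g` fits
$(\mu_a,\mu_s)$ only, and `fix_mu_s = 0` reduces to the exact Beer-Lambert
inverse $\mu_a = -\ln(T_c)/d$. A measured triplet of zeros is flagged as
diverging absorption rather than fitted.

Identifiability depends on the optical thickness: at 100 µm and $\mu_a
\approx 0.5\ \mathrm{cm^{-1}}$ the absorbed fraction is ~0.5%, below
Monte-Carlo resolution at $10^5$ photons, so recovery checks use a 500 µm
slab with $\mu_a = 2\ \mathrm{cm^{-1}}$ where all three parameters are
resolvable.

## Porosity and mechanics

`bin_pores()` uses half-open decade bins $[0,10), \ldots, [70,80)$ µm — the
conventional grouping for these histograms; published bin labels overlap at
the boundaries, so the half-open convention is a deliberate choice, with
out-of-range diameters counted separately rather than silently dropped.
`fit_lognormal()` fits $\mathrm{scale}\cdot\mathrm{LogNormal}(x;\mu,\sigma)$
to the counts at bin midpoints by Levenberg-Marquardt least squares (moment
starting values), because the histogram curve — not the raw diameters — is
the published object; an MLE on raw diameters would be the alternative when
diameters are available. $R^2$ is computed against the count variance and is
undefined (reported `NA`) for exactly uniform counts.

`bulk_density()` ($\rho = m/V$), `elastic_modulus()` ($E = \sigma/\epsilon$)
and `pva_weight()` are direct formula implementations. The PVA recipe weight
is the product `concentration * volume / 100` — the published formula prints
a minus sign, but its own worked value (7% in 150 mL giving 10.5) requires
the product — and the result is labeled "mg" as printed even though the
magnitude is physically grams; the package reproduces the printed numbers
and flags the unit in the documentation.

## Problem sizes and determinism

The bundled tests and the acceptance script run entirely on synthetic data
generated in code: identification studies use 2000-sample records (about 65
periods at 30 samples per period), Monte-Carlo optics use $10^5$-photon
forward runs against $10^6$-photon references, and pore-size recovery uses
$10^4$ draws. These sizes put every stochastic check well inside its
tolerance while keeping a full run under a minute. Every stochastic function
takes a single integer seed and restores the caller's RNG state; identical
seeds give byte-identical outputs end to end.

## Known limitations

* Output-only identification cannot separate the gain from the initial
  state; the reported gain is a least-squares scale match of the closed-form
  response on the fit window.
* The damping ratio of a real hydrogel trace reflects the full acoustic
  path, not the gel alone; comparisons across samples assume a common
  measurement geometry.
* The Monte-Carlo slab omits sphere geometry; inverted coefficients are
  consistent within this forward model and should not be compared against
  sphere-corrected literature values without that caveat.
* Critically damped and overdamped regimes are detected (the extraction
  returns $\zeta = 1$ for real stable poles) but not simulated.
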
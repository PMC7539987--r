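---
title: "Models and methods behind xanthoq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xanthoq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xanthoq)
```

`xanthoq` couples a mechanistic model of the xanthophyll cycle to the
analysis stages that measure its operation. This vignette explains the
model, the defaults and the reasoning behind each design choice, and what
the synthetic-data tests do and do not demonstrate.

## The kinetic core

### De-epoxidation chain

Violaxanthin de-epoxidase (VDE) removes the two epoxide groups of
violaxanthin sequentially:

$$\frac{d[\mathrm{Vio}]}{dt} = -k_{de1}\,a(\mathrm{pH})\,g\,[\mathrm{Vio}],
\qquad
\frac{d[\mathrm{Ant}]}{dt} = k_{de1}\,a\,g\,[\mathrm{Vio}] - k_{de2}\,a\,g\,[\mathrm{Ant}],
\qquad
\frac{d[\mathrm{Zea}]}{dt} = k_{de2}\,a\,g\,[\mathrm{Ant}],$$

with $a(\mathrm{pH}) \in [0,1]$ the normalized pH-activity of the enzyme
and $g$ the dithiothreitol (DTT) inhibition factor ($g = 1$ without
inhibitor; the default `dtt_inhibition = 0` encodes the complete
inhibition observed at 1 mM DTT). The chain conserves the total
xanthophyll pool exactly; the integrator keeps the numerical drift below
$10^{-6}$ relative (`lsoda`, rtol $10^{-8}$).

Because the violaxanthin equation is autonomous, the fraction of
violaxanthin consumed after time $t$ is $1 - e^{-k_{de1} a g t}$
independent of $k_{de2}$. "Conversion efficiency" is therefore defined as
violaxanthin consumed, $1 - \mathrm{Vio}(t)/\mathrm{Vio}(0)$, the reading
that matches how de-epoxidation efficiency is usually quoted; counting
zeaxanthin produced instead is available via
`conversion_fraction(sim, "produced")` — the two coincide when the second
step is fast.

**Calibration.** The shipped defaults set $k_{de2} = k_{de1}$ and solve for
$k_{de1}$ by a one-dimensional root find against the simulated 60-min
assay at pH 5.1 (0.33 µM violaxanthin), targeting 95% conversion for the
*A. thaliana* enzyme and 77% for *C. vulgaris*. Only these end points are
observationally constrained; the split between the two steps is a
modelling convention.

### pH-activity profile

The activity curve is a product of two logistic terms — an acid-side rise
and an alkaline-side fall — translated so its analytic maximum sits
exactly at `ph_opt` (5.1 for both shipped species) and scaled to 1 there.
A raw two-logistic product with unequal slopes peaks slightly off its
nominal centre; the translation makes "activity is exactly 1 at the
optimum" a structural property rather than an approximation, so the grid
argmax is stable at any grid resolution. The *C. vulgaris* profile uses a
much steeper alkaline slope (6 vs 2 pH$^{-1}$) and tighter logistic
spacing, encoding the chlorophyte enzyme's sharply reduced activity at
neutral pH; at pH 7 it retains less than 0.1% activity versus ~15% for the
plant enzyme. The acid side below pH 5.1 is not constrained by enzyme
data; its slope (3 pH$^{-1}$) is a free convention, and the supported
evaluation domain is pH 3–9.

A side effect worth knowing: the logistic tail never reaches exactly zero,
so dark (pH 7) in-vivo trajectories show a residual de-epoxidation flux of
order $10^{-5}$ DI over 10 minutes. Tests treat anything below $10^{-3}$
as "no driving force".

### In-vivo operation

In vivo three extra processes join the chain:

* **Lumen pH.** Steady-state lumen pH decreases with irradiance $I$ as
  $\mathrm{pH}_{ss}(I) = 7.0 - 2.0\, I / (I + K_I)$ with
  $K_I = 500$ µmol m$^{-2}$ s$^{-1}$, approached with a first-order time
  constant of 30 s. This coupling is package plumbing — lumen pH is not
  measured here — chosen so that saturating light acidifies the lumen into
  the range where VDE and qE activate.
* **Epoxidation.** Zeaxanthin epoxidase reverses the cycle
  (Zea→Ant→Vio) at $k_{ep} = 0.02$ min$^{-1}$, slow enough that less
  than 15% of accumulated zeaxanthin is reconverted during a 5-min dark
  interval — which is what lets zeaxanthin persist between light cycles
  and boost quenching in a second illumination.
* **Membrane rate scale.** The reconstituted micellar assay underestimates
  in-situ turnover; in vivo the de-epoxidation constants are multiplied by
  `vivo_rate_scale` (default 4), chosen once so that 25 min at
  2000 µmol m$^{-2}$ s$^{-1}$ drives DI to ≈ 0.6, the ceiling observed at
  the highest irradiances in vivo.

### Quenching model

Three components evolve as ODEs and sum to NPQ:

* **qE** (amplitude 1.6): induction $\propto$ a steep lumen-pH switch
  (logistic midpoint pH 6.0, width 0.15) times a saturating zeaxanthin
  term $z/(z + K_z)$ with $K_z$ = 4% of the xanthophyll pool, time
  constant ~30 s; relaxation ~60 s once the pH switch releases. The small
  $K_z$ makes qE saturate after very little de-epoxidation — few
  zeaxanthin molecules are needed to arm the fast component — which is
  also what gives qE the highest asymptotic-correlation rate in the
  irradiance sweep.
* **qZ** (amplitude 1.0): relaxes toward $q_{Z,max}\cdot z$ (zeaxanthin
  fraction of the pool) with a 300-s time constant; in the dark it decays
  only as fast as epoxidation removes zeaxanthin, making it the slowly
  relaxing, nearly DI-linear component.
* **qI** (amplitude 0.45): builds with light dose (saturating in
  irradiance, ~10-min induction) and relaxes with a 2-h time constant;
  zeaxanthin-independent, so it is the quenching that survives DTT.

The amplitudes and time constants are set to reproduce the qualitative
study conditions — NPQ ≈ 2.3 at 2000 µmol m$^{-2}$ s$^{-1}$ with strong
DTT sensitivity and a persistent dark fraction — not fitted to any printed
trace.

## Analysis stages

**HPLC quantification.** Peak detection finds local maxima above a
prominence threshold (default 5 mAU), integrates trapezoidally between the
bounding valleys after subtracting a linear baseline drawn between them
(areas are thus invariant to uniform offsets), and maps areas to
concentrations by per-pigment linear response factors inside
non-overlapping retention windows. Windows and factors are synthetic
conventions shipped as config (`default_calibration()`); real instruments
require their own calibration table. Two peaks in one window raise an
ambiguity error listing both; a missing peak reports zero with a
below-detection flag.

**PAM processing.** Fm (and each Fm′) is the maximum within ±0.4 s of the
annotated pulse; ties take the first sample and are logged. Fo is the
median pre-pulse dark signal. The qE/qI(qZ) split follows the standard
relaxation partition: the slowly relaxing fraction is NPQ at the last
dark-recovery pulse, qE the difference to NPQ at the last pulse in light —
so qE + qI/qZ equals end-of-light NPQ by construction. Whether the end
points use the last pulse or the mean of the last *k* pulses is
configurable (`endpoint`, default last). Far-red illumination during
recovery is not modelled; dark recovery is treated purely as quenching
relaxation.

**77 K deconvolution.** Spectra are normalized so the integrated
internal-standard (GFP) band area over 500–540 nm is 1, then fitted with
four Gaussians — PSII at 686 and 698 nm, PSI at 720 nm, one vibronic
satellite near 745 nm — by bounded Levenberg–Marquardt (centers within
±5 nm of their initial values, positive widths and areas via log-amplitude
parametrization). The quenching statistic is
$(A_{dark} - A_{light})/A_{light}$ per photosystem, dividing by the
light-treated area; the more common $A_{dark}$ denominator is available
via `convention = "dark"`. The vibronic band is excluded from both sums.
The exact number of bands beyond the three named ones is configurable.

**Lifetime fitting.** The decay model is a sum of exponentials convolved
with a Gaussian IRF, evaluated analytically (exponentially modified
Gaussian) and wrapped once at the 20-ns repetition period of a 50-MHz
laser. When a measured IRF accompanies the histogram its first two moments
set the Gaussian's center and width; otherwise a configurable FWHM is used
(default 30 ps streak-style; 120 ps is typical for TCSPC). Fitting is
Poisson-weighted least squares from the IRF peak bin onward, lifetimes and
amplitudes positive via log parametrization. Average lifetime is
amplitude-weighted, $\sum a_i\tau_i$ — the convention appropriate when
amplitudes count emitters — with the intensity-weighted alternative always
reported alongside. The reference PSI component sets (55/135 ps and
35/95 ps, two exponentials) are conventions solved exactly for
amplitude-weighted means of 72 ps (zeaxanthin-free) and 49 ps
(zeaxanthin-binding); only those averages are constrained by measurement.

**DI–NPQ correlation.** The saturating form
$y = y_{max}(1 - e^{-rate\cdot DI})$ is the simplest two-parameter
"exponential asymptotic" curve through the origin; an optional intercept
exists but the default forces the origin (no quenching without any
de-epoxidation, consistent with the DTT observations). Initialization
profiles the rate over a log grid with the amplitude solved linearly,
then polishes by Levenberg–Marquardt, which removes sensitivity to
starting values. On the default sweep (200–2500 µmol m$^{-2}$ s$^{-1}$,
single-cycle protocol) the fitted rates order qE > NPQ > qI/qZ.

## Synthetic data: what it shows and what it does not

Each generator inverts exactly one analysis stage: PAM pulse heights are
$F_m/(1 + \mathrm{NPQ}(t))$ with multiplicative Gaussian noise (default
0.5%, typical of modulated fluorometers); spectra are Gaussian band sums
with 1% multiplicative noise; chromatograms are Gaussian peaks (σ =
0.08 min) with 0.5 mAU additive baseline noise; decays are Poisson draws
around the IRF-convolved model scaled to 10⁴ peak counts. All randomness
flows through the single `noise_spec` seed, and generators restore the
global RNG state.

Passing round-trip tests therefore demonstrates internal consistency —
estimator correctness, absence of bias at realistic noise, determinism —
not field realism. Real instruments add what the generators omit:
baseline drift and co-elution in HPLC, actinic artefacts and far-red
effects in PAM, detector response and wavelength calibration error at
77 K, IRF asymmetry and afterpulsing in TCSPC. The analysis stages carry
the hooks (configurable windows, calibrations, IRF input) but their
defaults are tuned to the synthetic conventions.

## Numerical choices and problem sizes

* ODEs: `deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$ (scaled for the
  in-vitro micromolar range), fixed 1-s output grid in vivo, 601 points
  in vitro. The simulator is fully deterministic.
* Nonlinear fits: `minpack.lm::nls.lm` with box bounds; log
  parametrization enforces positivity smoothly; convergence failures
  raise classed errors carrying diagnostics rather than returning silent
  garbage; degenerate decay fits (amplitude < 1% or lifetime ratio
  < 1.2) are flagged, not hidden.
* Units: minutes for in-vitro kinetics, seconds in vivo, ps for decays;
  concentration units travel as labels and are never converted
  implicitly.
* Test suite sizes: 100-seed recovery studies for decays and
  chromatograms, 200 seeds for the asymptotic-fit bias study, 25 seeds
  for the generic two-exponential recovery check; the full suite runs in
  about half a minute on one core.

## Known limitations

* The lumen-pH coupling is phenomenological; no electron-transport or
  ΔpH thermodynamics.
* qE, qZ and qI are operational first-order components; state
  transitions (qT) and PSII repair are out of scope.
* Single-wavelength HPLC quantification; no co-elution deconvolution or
  spectral library matching.
* No global/target analysis across emission wavelengths for decays, and
  no lifetime-distribution methods.
* The acid side of the pH-activity curve and the decay component
  structure are conventions constrained only at the points stated above.
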
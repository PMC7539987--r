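# xanthoq

Simulation and analysis of xanthophyll-cycle driven photoprotection in
green algae and plants.

When photosynthetic organisms absorb more light than they can use, they
dissipate the excess as heat — non-photochemical quenching (NPQ). A central
trigger is the xanthophyll cycle: at low lumen pH the enzyme violaxanthin
de-epoxidase (VDE) converts violaxanthin (Vio) to zeaxanthin (Zea) in two
steps via antheraxanthin (Ant); zeaxanthin epoxidase slowly reverses the
cycle in the dark. `xanthoq` packages a mechanistic model of this cycle for
*Chlorella vulgaris* (an industrially important microalga with a plant-type,
DTT-sensitive VDE) and *Arabidopsis thaliana*, together with the analysis
stages used to study it experimentally. It is aimed at photosynthesis
researchers who want a tested, reproducible pipeline for pigment, PAM,
low-temperature fluorescence and lifetime data — and a ground-truth
simulator to validate that pipeline against.

## What it computes

**Xanthophyll-cycle kinetics.** De-epoxidation is modelled as the linear
chain dVio/dt = −k₁·a(pH)·Vio, dAnt/dt = k₁·a(pH)·Vio − k₂·a(pH)·Ant,
dZea/dt = k₂·a(pH)·Ant, where a(pH) is the normalized VDE pH-activity curve
(maximum 1 at pH 5.1) and DTT multiplies the VDE rates by an inhibition
factor (0 = complete inhibition). The shipped rate constants are calibrated
so the simulated 60-min reconstituted assay at pH 5.1 converts 95%
(*A. thaliana*) and 77% (*C. vulgaris*) of 0.33 µM violaxanthin. In vivo,
lumen pH follows irradiance with first-order relaxation, and three
quenching components are integrated alongside the pigments: qE (fast,
pH- and zeaxanthin-activated), qZ (tracks zeaxanthin, slowly relaxing) and
qI (light-dose dependent, very slowly relaxing), with
NPQ = qE + qZ + qI.

**Derived statistics.**

* De-epoxidation index DI = ([Zea] + 0.5[Ant]) / ([Zea] + [Ant] + [Vio])
* NPQ = (Fm − Fm′)/Fm′ and Fv/Fm = (Fm − Fo)/Fm from saturating-pulse PAM
  traces, with the relaxation-based split into qE and the slowly relaxing
  fraction (qI/qZ)
* PSII and PSI quenching at 77 K, (A_dark − A_light)/A_light, from Gaussian
  deconvolution of emission spectra (bands at 686, 698, 720 nm plus a
  vibronic satellite, GFP internal-standard normalization)
* Amplitude-weighted average lifetimes ⟨τ⟩ = Σaᵢτᵢ from IRF-convolved
  multi-exponential fits of photon-counting decays
* The asymptotic-exponential correlation y = y_max(1 − e^(−rate·DI))
  between de-epoxidation and each NPQ component across irradiances

**Synthetic instruments.** Seeded generators emulate every modality the
analysis consumes (PAM traces, 77 K spectra, TCSPC decays, HPLC
chromatograms, assay absorption spectra), each wired to simulator ground
truth, so every stage has a measurable round-trip test.

## Worked example

```r
library(xanthoq)

model <- default_kinetic_model("c_vulgaris")
simulate_in_vitro(model, ph = 5.1, vio0 = 0.33, t_end = 60)
#> Xanthophyll-cycle simulation (in_vitro, 601 points, min)
#>   t = [0, 60] min
#>   DI: 0.0000 -> 0.6010
#>   conversion fraction (consumed): 0.7700

sim <- simulate_in_vivo(model, npq_protocol(irradiance = 2000))
sim
#> Xanthophyll-cycle simulation (in_vivo, 2221 points, s)
#>   t = [0, 2220] s
#>   DI: 0.0000 -> 0.5301
#>   final NPQ 0.710 (qE 0.004, qZ 0.381, qI 0.325)

trace <- gen_pam_trace(sim, noise = noise_spec(seed = 1))
npq_analysis(trace)
#> NPQ analysis
#>   Fm = 2.009, Fv/Fm = 0.801
#>   NPQ at end of light = 2.280 (qE 1.565, qI/qZ 0.715)
```

The in-vitro run reports that 77% of the violaxanthin was consumed in 60
minutes — the calibrated *C. vulgaris* assay efficiency. The in-vivo run
drives 25 min of 2000 µmol m⁻² s⁻¹ light followed by 10 min of dark: DI
climbs to ~0.6, NPQ reaches ~2.3 at the end of light and relaxes to ~0.7
after dark recovery (the persistent fraction carried by zeaxanthin and
photoinhibition). The synthetic PAM trace analysed back through the pulse
pipeline recovers those values, plus Fv/Fm ≈ 0.8 for the dark-adapted
state.

A command-line interface with the same functionality is installed at
`system.file("exec", "xanthoq", package = "xanthoq")`, with subcommands
`simulate`, `npq`, `quench77k`, `lifetime`, `pigments`, `correlate` and
`generate`.

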
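---
title: "Modelling a plasmonic organic photovoltaic epiretinal prosthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a plasmonic organic photovoltaic epiretinal prosthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmopv)
```

## The device and the modelling question

`plasmopv` models a photovoltaic pixel for an epiretinal prosthesis: a
PCPDTBT:PCBM bulk-heterojunction layer (L = 70 nm) that converts pulsed
light into current, loaded with two populations of silver nanospheres.
Small spheres embedded in the active layer (radius r = 5–10 nm, volume
filling fraction f_s ≤ 10%) act as near-field antennas at their localized
surface plasmon resonance (LSPR); a monolayer of larger spheres
(R = 25 nm, interparticle gap d = 1–5 nm) replaces the planar cathode,
acting simultaneously as the stimulation electrode and as a second
plasmonic absorber. The chain of questions the package answers is:

1. How much light do the embedded particles absorb, and where is their
   resonance? (quasi-static dipole optics)
2. How much light survives the trip through the loaded active layer to the
   cathode monolayer? (Beer–Lambert attenuation)
3. How much short-circuit current does the composite structure generate?
   (a three-term photocurrent model)
4. What operating point does the pixel reach against the
   electrode–electrolyte interface, and does that current stimulate a
   retinal ganglion cell axon? (single-diode circuit + load line;
   Hodgkin–Huxley cable)

The package is a desk-scale reimplementation: the original device study
used finite-element electromagnetic, semiconductor and tissue solvers for
stages that are replaced here by calibrated reduced models. Each
substitution is stated below together with what it can and cannot
reproduce.

## Optical-constant fixtures and the calibration philosophy

All optics are driven by three packaged n,k tables (250–800 nm, 1-nm
steps): `silver`, `active_blend` and `water` (`load_optical_constants()`).
Water is dispersionless (n = 1.33). The silver table is a Drude model
(eps_inf = 3.7, plasma energy 9.01 eV) and the blend combines a Cauchy
index with a two-Gaussian extinction band (UV band at 250 nm, visible
shoulder at 500 nm).

These tables are **calibrated synthetic stand-ins**, not literature
digitizations, and the calibration is the load-bearing design decision of
the package. Four observable anchors pin them
(`compute_calibration()`, frozen in `inst/extdata/calibration.yaml`):

* blend k(453) and k(250) are set so the bare-layer short-circuit current
  J_sc = (q L λ I₀/hc) · P · α₁ reproduces the reference values
  7.5 A/m² (453 nm) and 19 A/m² (250 nm) at 0.26 mW/mm²;
* the silver damping γ and the blend Cauchy offset are solved jointly so
  the quasi-static absorption peak of an r = 10 nm sphere in the blend
  sits exactly at 453 nm with peak Q_abs = 2.4.

Everything else the optics produce — the Q_abs values 1.2/1.8 for
r = 5/7.5 nm, the peak Q_scat triple 0.0012/0.0058/0.019, the scattering
efficiencies 0.001/0.003/0.008 — is then a *prediction* of the dipole
formulas, not a fit: in the quasi-static limit Q_abs is exactly linear in
r and Q_scat/Q_abs scales as the particle volume, so one anchor per curve
family fixes the whole set.

Two consequences are worth stating plainly. First, the calibrated silver
is much lossier at 453 nm (Im ε ≈ 1.9) than tabulated crystalline silver
(≈ 0.2); an ideal-metal fixture would give peak Q_abs ≈ 17, far above the
device-level value the calibration targets, so the damping absorbs every
loss channel the dipole picture omits. Second, the resonance of a lossy
sphere peaks slightly blue of the exact Fröhlich crossing
Re(ε_m) = −2 Re(ε_s); the package centres the *peak* at 453 nm and the
crossing lands a few nanometres red of it.

**Wavelength convention.** The cross-section prefactors use the vacuum
wavelength: C_abs = (2π/λ) Im α, C_scat = (1/6π)(2π/λ)⁴|α|². The
in-medium alternative λ/n_s is one flag away
(`cross_sections(..., medium_wavelength = TRUE)`). Vacuum is the default
because it is the only convention consistent with the anchored magnitude
pair (Q_abs, Q_scat) = (2.4, 0.019) for r = 10 nm: with in-medium
prefactors the same Q_abs forces peak Q_scat ≈ 0.066, 3.5× the reference
value.

## Beer–Lambert attenuation: two calibrated conventions

`total_transmittance()` composes two channels and records every
intermediate. The **layer channel** is T = exp(−α₁ (1−f_s) x_eff) with
α₁ = 4πk/λ. The effective path x_eff ≈ 377 nm (≈ 5.4 L) is calibrated so
T(453 nm, f_s = 7.5%) = 0.57: with the photocurrent-calibrated α₁ the
geometric thickness would give T ≈ 0.89, irreconcilable with the 56–58%
transmittance band the device study reports. The two calibrations (k from
photocurrent, path from transmittance) are deliberately kept independent
rather than silently merged; the absorber is diluted by (1−f_s) only,
which reproduces the reported widening 56→58% as f_s grows.

The **nanoparticle channel** follows the molar-absorptivity route:
ϵ = N_A σ/2.3×10³ with σ = C_abs/N the per-atom cross-section, and
T = 10^(−ϵcl) with l = L. The atomic concentration c is f_s times the
bulk silver atomic density, multiplied by a coupling factor κ_np·f_s
anchored once at T(f_s = 10%) = 94.6%. The extra factor proportional to
f_s makes the optical depth quadratic in the filling fraction; a strictly
linear law cannot pass through the reported triple 99/97/94.6% (it is
log-quadratic in f_s to within 0.4 points, and the best linear fit
misses by 1.15 points). Physically the factor stands for inter-particle
near-field coupling at higher loading; it is a calibrated convention, and
the audit report (`attenuation_result`) exposes it.

## The composite photocurrent

`jsc_composite()` implements the three-term model

J_sc = (I₀ λ q L/hc) · [ 0.70 α₁ (1 − f_s − v₁f_s − v₂)
  + 0.85 α₂ (1 − Q_sc) v₁ f_s κ_A + k · 0.85 α₂ v₂ κ_K ]

with dissociation probabilities 0.70 (bare blend) and 0.85 (blend within
a particle's near field), α₂ = 4π k_Ag/λ the metallic absorption
coefficient, and k = T_r × A_b the fraction of incident light that
reaches and is absorbed by the cathode monolayer (T_r from the
attenuation stage, A_b from the cathode-array stage). Scattering terms
are omitted throughout: at these particle sizes Q_sc ≤ 0.008, and the
(1−Q_sc) factor in the near-field term is the only trace scattering
leaves.

Two geometric conventions close the model:

* **v₁ = Q_abs^{3/2}** — the near-field influence region is the sphere
  whose cross-sectional area equals C_abs. This convention is validated
  by an independent observable: the reference J_sc-versus-f_s slopes for
  r = 5/7.5/10 nm stand in the ratio 1 : 1.8 : 2.8, and
  Q_abs^{3/2} = (1.2, 1.8, 2.4)^{3/2} gives 1 : 1.84 : 2.83.
* **v₂ = C_abs(K) · L_inf / (A_site · L)** — one cathode particle per
  hexagonal site of area (√3/2)(2R+d)², each projecting its absorption
  cross-section (1500 nm² at the 1.5-nm gap) over an influence depth
  L_inf = 25 nm (the particle radius; any other choice is absorbed into
  κ_K).

The absolute scales of terms two and three are under-determined by the
model prose, so each carries one dimensionless calibration constant,
fitted once and frozen: κ_A at the single point (r = 5, f_s = 5%, with
cathode, 0.26 mW/mm² → 15 A/m²) and κ_K at the single with/without
cathode pair (r = 7.5, f_s = 10%, 0.33 mW/mm² → 36 vs 33 A/m²). The
remaining sixteen reported grid values are genuine out-of-sample
predictions, and the test suite requires each within ±2 A/m². The
K-term uses the scenario's own T_r, which drifts ~1.5% across f_s; the
reference grids show an f_s-independent increment, and the residual is
within the ±2 A/m² band.

## Device circuit and electrode load line

The drift-diffusion device solve is replaced by a single-diode equivalent
circuit fitted **per configuration** to its reported (J_sc, V_oc, FF)
triple (`calibrate_diode()`): J₀ follows analytically from V_oc, the
ideality factor is the unique root matching FF, and series/shunt
resistance stay ideal (the reported fill factors 75.2–80% at
V_oc ≈ 0.68–0.69 V all lie inside the span the ideality alone covers,
n ≈ 1.4–1.9). A single fixed-parameter diode cannot reproduce the
reference table — V_oc moves only 20 mV across a 5× J_sc range — which is
why the fit is per configuration. Curves are evaluated on a 1-mV grid
from 0 to 1.1 V_oc; the intersection with the electrode load line
J = V/Z (Z = 4.3 kΩ·mm², from the threshold pair |−0.11 V|/25.1 A/m²) is
found by bisection to 1e-9 V. The activation verdict compares the
operating-point current density with the 25.1 A/m² threshold; 1.23 V is
the water-window safety bound on electrode potentials.
`threshold_intensity()` exploits the linearity of J_sc in intensity to
bisect for the dimmest stimulating illumination (resolution
0.005 mW/mm²).

## The cathode monolayer: reference table and coupled dipoles

The far-field behaviour of the K-AgNP monolayer is served two ways.
The **reference table** carries the reported feature values (absorptance
peaks 68/65/58/50% for gaps 1/1.5/2.5/5 nm, reflectance minima,
transmittance peaks, and the 1500 nm² per-particle cross-section at
453 nm for the selected 1.5-nm gap). It holds spot values only and
refuses off-anchor queries rather than interpolating. It is the default
A_b source for the photocurrent, so the headline J_sc numbers rest on the
reported absorptance, not on the reduced model.

The **coupled-dipole mode** is the computable substitute: each sphere is
a point dipole with the quasi-static polarizability; the hexagonal
lattice coupling is the quasi-static in-plane dipole sum, truncated at 50
pitches with a cosine² taper and a convergence check; and the specular
response of the dipole sheet gives R = |r|², T = |1+r|² with
r = i(k/2A_c)α_eff. For a subwavelength pitch the imaginary part of the
lattice sum is fixed exactly by energy conservation
(Im S = k/2A_c − k³/6π), so A = 1−R−T ≥ 0 holds to machine precision by
construction — absorptance is never obtained from an independently
truncated sum. The retarded form of the sum was evaluated and rejected:
at pitch/λ_med ≈ 0.2 the oscillatory factor suppresses the near-field
coupling and washes out the gap-resolved resonance structure.

What the mode reproduces: interior array resonances red-shifted from the
isolated-particle LSPR, blue-shifting monotonically as the gap grows
(443/441/439/431 nm for gaps 1/1.5/2.5/5), exact energy conservation,
and the dilute-limit recovery of the radiative-corrected single-particle
cross-section (within 5% across the whole band at the radiation-matched
pitch ≈ 150 nm, and away from resonance at pitch 10R). What it cannot
reproduce: the absolute peak absorptances (it reaches ~0.23–0.27, not
0.5–0.68) and their decreasing order with gap. Both failures have one
cause: at 1–2.5 nm gaps the real structure absorbs in near-field
hot-spots between spheres, a channel outside any point-dipole
description, while the dipole sheet is over-coupled (its radiative
channel k/2A_c exceeds the particle loss channel), making denser arrays
more reflective instead of more absorbing. The corresponding check in
the acceptance suite is left failing deliberately, as a statement of this
limitation; at resonance the infinite array's collective specular damping
also differs irreducibly from the isolated-dipole damping k³/6π, which
bounds the dilute-limit agreement near the peak.

## Neural activation: plate field and axon cable

The proprietary tissue/neuron engine is replaced by two standard pieces,
and only property-level fidelity is claimed — the package never asserts
the −0.11 V threshold value itself.

The **plate field** is a method-of-moments solve of the 100×100 µm
equipotential plate in a half-space of conductivity 0.027 S/m (the 10-Hz
tissue permittivity is folded into the resistive solution): 24×24
patches (at least 20 per side enforced), 1/(2πσR) kernel, self-terms by
16×16 subdivision. The sampled current-density profile shows the classic
signature — sharp edge peaks flanking a central plateau — and scales
linearly in drive voltage and conductivity. The geometric area is used
directly; the effective-area expansion a sphere-decorated electrode might
justify is not reconstructible from first principles and is deliberately
not applied.

The **axon** is a 400-µm, 1-µm-diameter unmyelinated cable (100
compartments of 4 µm; ≤ 5 µm enforced) with classical Hodgkin–Huxley
kinetics at their native 6.3 °C parameters, driven extracellularly
through the activating-function coupling: the axial term acts on
V_i + V_e with V_e the plate potential along the fibre. Integration is
operator-split and deterministic — exact exponential gating updates,
implicit tridiagonal cable solve (Thomas algorithm), dt = 25 µs, sealed
ends. `threshold_search()` bisects the cathodic amplitude to 1 mV.

Passing tests establish: rest stability under zero field, all-or-none
behaviour with full-height propagating spikes in both directions,
strength–duration monotonicity (0.5/1/2 ms), monotone threshold in
electrode standoff (5 vs 10 µm), and < 5% threshold change under
simultaneous halving of compartment length and time step. They do not
establish quantitative thresholds for real retinal ganglion cells: the
channel set, temperature and fibre geometry are the classical textbook
ones, chosen for reproducibility, not biological specificity.

## Numerical choices, problem sizes, determinism

* Wavelength grids: fixtures tabulate 250–800 nm at 1 nm; spectra and
  peak searches use 300–800 nm at 1 nm; resonance ties break toward the
  shorter wavelength (`which.max`). Array spectra in tests use 2-nm grids
  over 341–701 nm.
* All calibration root-finds are bracketed bisections on smooth 1-D
  functions with fixed brackets and tolerances (`uniroot`, tol ≤ 1e-10),
  so the frozen constants regenerate to ≥ 6 significant digits on any
  platform; a test compares the frozen file against a full recomputation.
* The pipeline has no stochastic stage: re-running a scenario is
  byte-identical, which the suite asserts.
* Degenerate inputs fail loudly: wavelengths outside the fixture range
  (no extrapolation), unbracketed resonances, zero extinction ratios,
  negative absorber fractions in the photocurrent (no silent clipping),
  non-subwavelength array pitches, unconverged lattice sums, and
  fill fractions above 10% — the loading where the blend morphology
  degrades and the model's validity ends.
* Typical runtimes on one CPU: the optical/photocurrent chain is
  milliseconds; a full scenario report well under a second; one axon
  threshold search a few seconds (≈ 8 cable simulations of 100 × 640
  steps).

## What the synthetic data do and do not emulate

The fixtures emulate smooth visible-band dispersion with the device's
resonance structure and device-level absorption magnitudes. They do not
carry silver's interband structure below ~320 nm, temperature or
deposition dependence, size-dependent damping, or the blend's true
vibronic absorption shape — only the two calibrated wavelengths (453 and
250 nm) of the blend's extinction are observationally anchored, and
intermediate wavelengths are smooth interpolations. Model predictions at
untested wavelengths inherit that status. Within those bounds, the green
test suite shows the *relations* of the model chain (linearity,
monotonicity, volume scalings, conservation laws, all-or-none
excitability) and its anchored magnitudes; it does not show agreement
with measurements of a fabricated device.
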
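---
title: "Monte Carlo methods for spot-scanning aperture dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo methods for spot-scanning aperture dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssadose)
```

## The problem

Pencil-beam-scanning (PBS) proton machines cannot produce beams below about
70 MeV, so shallow targets (< 4 cm water-equivalent) are treated through a
range shifter. A range shifter mounted far upstream (the *extended range
shifter*, ERS) inflates the in-water spot size through multiple Coulomb
scattering followed by a long air drift, degrading lateral dose resolution
exactly where it matters most — shallow head-and-neck targets surrounded by
organs at risk. A *spot-scanning aperture* (SSA) is a small collimator with a
single cylindrical bore, carried by a robot so that its opening follows every
spot; a range shifter rides on its upstream face. `ssadose` is a desk-scale
simulation pipeline for the dosimetric consequences of that design: spot
size, integrated depth dose (IDD), dose-averaged LET, beamlet transmission,
secondary neutron dose and delivery-time overhead, as functions of the
aperture material, bore radius, aperture-to-surface distance (ASD) and
range-shifter gap.

## Transport model

Protons are tracked one at a time through an axial slab stack — air, range
shifter, air gap, aperture slab with a cylindrical bore, air (the ASD), and a
voxelized water phantom — with a condensed-history model:

* **Energy loss.** Mean loss per step from tabulated electronic mass stopping
  powers; the tables are computed from the Bethe formula (no shell or
  density-effect corrections) and shipped as plain-text fixtures. They match
  published reference values at the per-mille level for water at therapeutic
  energies (7.29 MeV cm²/g at 100 MeV; 40.8 mm CSDA range at 70 MeV);
  high-Z entries are accurate to a few percent, which is the dominant
  systematic on tungsten range quantities.
* **Straggling.** Gaussian (Bohr) energy-loss straggling per step, with the
  standard relativistic correction. The Gaussian sample is used only where
  the model is valid (σ of the step ≤ mean step loss); ultrathin air steps
  take the mean loss deterministically, because clipping a wide Gaussian at
  zero would bias the mean. No Landau/Vavilov tails: the distal-falloff
  width is slightly idealized.
* **Multiple Coulomb scattering.** Highland's formula with the logarithmic
  factor evaluated at the radiative thickness of the *whole slab* being
  traversed (Gottschalk's prescription), which keeps the per-step variance
  additive; correlated lateral displacement uses the standard
  (z/√12 + z/2) construction. Slopes are paraxial.
* **Nuclear interactions.** A simplified removal model: primaries are
  attenuated with a per-material mean free path (120 g/cm² in water, scaled
  per material), depositing 60% of the removed proton's energy locally and
  booking the remainder as escaped. This reproduces realistic
  peak-to-entrance ratios without a secondary cascade.
* **Aperture.** The aperture is a laterally infinite slab; at every step a
  proton is inside the bore iff its distance from the (possibly offset) bore
  axis is *strictly* less than the radius. Protons may cross between wall
  and bore mid-slab, which is the mechanism that produces the low-energy
  slit-scattered protons responsible for the entrance-dose and LET
  degradation of small bores.
* **Scoring.** Dose and dose-averaged electronic LET accumulators on a
  1×1×1 mm grid (half-open voxel ownership), energy bookkeeping per region
  (the sum of all deposits plus escapes equals the injected energy exactly),
  and the phase space at the aperture exit plane.
* **Reproducibility.** Every primary owns a counter-based RNG stream derived
  from `(seed, primary index)`; results are bit-identical for a given seed
  and independent of execution order.

Step sizes are at most 1 mm in water and plastic, 0.2 mm in metals and in
the bore region (to resolve wall re-entry), and 10 mm in air (10 mm of air
is ~0.01 mm water-equivalent, so this is a pure speed choice); each step is
also capped at 5% of the current energy. Protons below 1 MeV deposit their
residual energy locally.

## Beam model and synthetic data

The machine model is deliberately minimal: 17 nominal energies from 70 to
230 MeV, with an in-air spot σ at isocenter interpolated monotonically in
1/E between 6 mm (70 MeV) and 2 mm (230 MeV), zero divergence (a parallel
Gaussian beam) and a source plane 500 mm upstream of isocenter. All of
these are configurable; the divergence default is zero because every
comparative quantity studied here is dominated by range-shifter scattering
close to the phantom, not by the nozzle emittance. The range-shifter
material is polycarbonate (1.2 g/cm³) with a 45 mm water-equivalent
thickness by default; the WET is configurable per experiment, since a fixed
WET cannot reproduce every published figure simultaneously.

Synthetic treatment fields stand in for clinical plans: layers spaced 5 mm
in water-equivalent depth, a random elliptical cross-section per layer
(semi-axes 10–30 mm), spots on a 5 mm grid inside the ellipse, and
log-normal planned protons per spot (median 10⁷, one decade at two sigma).
They emulate the geometry and bookkeeping of real fields — eligibility
filtering, per-spot energies behind a range shifter, spot counts — but not
clinical optimization, heterogeneity or field-to-field correlations, so
conclusions drawn from them are about the *estimator*, not about any
patient population.

```{r beam, eval = FALSE}
bm <- beam_model()
sigma_air(bm, c(70, 150, 230))
plans <- generate_synthetic_plan(5, seed = 1)
```

## The quantities reported

For a paired run (identical source, aperture present vs replaced by air):

* **IDD** — lateral sum of dose per depth, optionally normalized to the
  first 1 mm bin ("entrance = 1"); the entrance bin is the convention used
  for every peak-to-entrance number here.
* **Bragg-peak depth** — maximum of the IDD refined by a parabolic fit
  through the three bins around the maximum.
* **Spot σ** — a Gaussian fitted (Levenberg–Marquardt) to the core of the
  lateral profile at the Bragg-peak depth, with the fit window limited to
  three times an initial RMS estimate. Collimated spots are not Gaussian;
  the fit-to-core mimics clinical σ reporting, and a plain RMS option is
  provided. Each configuration is evaluated at its own Bragg-peak depth.
* **Transmission** — total phantom dose with the aperture divided by the
  total dose of the identical no-aperture run; a dose ratio, not a proton
  count ratio.
* **ILD** — dose-averaged electronic LET along the central-axis voxel
  column, with the stopping power evaluated mid-step (1 MeV/mm ≡ 1 keV/µm).

```{r worked, eval = FALSE}
cfg <- ssa_config(material = "tungsten", bore_radius_mm = 3,
                  asd_mm = 50, bp_depth_mm = 50, n_histories = 1e5)
pair <- simulate_configuration(cfg, seed = 1)
spot_metrics(pair)
```

## Neutron estimator

Neutrons are not transported. A thick-target yield parameterization
Y(E, material) = Y₂₃₀ (E/230)^b (neutrons per stopped proton) is combined
with a two-component (isotropic + forward-peaked) point kernel integrated
over the front face of a 20 cm diameter water phantom. The amplitudes and
exponents are calibrated once — they are a synthetic fixture, not measured
data — such that nickel produces 62–70% of the tungsten phantom dose at
equal maximum treatment depth (70% at 230 MeV), with lead and brass ordered
between nickel and tungsten. Relative doses between materials and depths
are therefore meaningful by construction and validated as such; absolute
grays are order-of-magnitude only. Physical dose is reported, never
sieverts.

The per-field integral estimator rescales each spot's fluence to P/T (so
the protons *passing* the aperture match the plan), books P(1/T − 1)
protons as absorbed, evaluates the yield at the spot's aperture-incident
energy (nominal energy degraded by the range-shifter WET) and sums. Fields
qualify only if their water-equivalent treatment depth starts below 40 mm
and ends above no more than 100 mm.

The aperture block thickness criterion used throughout ("minimum stopping
thickness") is: the depth at which a straggling-convolved depth-dose curve
in water falls to 0.1% of its Bragg-peak value, plus 5%, converted into the
material through the range tables. For a 100 mm residual water range this
gives 11.2 mm of tungsten and 17.6 mm of nickel.

## Delivery time

A device that moves to every spot at constant speed v over spacing x adds
t_add = N·x/v: 10 s per 1000 spots at 5 mm and 500 mm/s. Acceleration and
deceleration are deliberately ignored — they are hardware-specific and
would require measurement.

## Design choices that were genuinely open

* **Stopping-thickness "plus 5%".** Interpreted as multiplicative on the
  0.1%-falloff depth *in water*, converted to the material via the range
  tables (the range-ratio conversion is the physically correct one for
  actually stopping protons; a scalar relative-stopping-power conversion
  would give ~2% thinner blocks).
* **σ reporting.** Gaussian fit-to-core by default, RMS as an option; the
  choice matters at the few-percent level for strongly collimated spots.
* **Default aperture thicknesses.** 11.1 mm (tungsten) and 18.5 mm (nickel),
  the reference design values; other materials fall back to the computed
  stopping-thickness criterion.
* **Comparator definitions.** "Open beam" = no device at all; "extended
  range shifter" = 45 mm WET shifter with its exit face 300 mm upstream of
  isocenter; "moveable range shifter" = the same shifter with its exit at
  the device position (the ASD), no aperture.
* **Aperture-incident energy** for neutron yields: the nominal energy
  degraded by the range-shifter WET (the range shifter sits upstream of the
  aperture in this design).

## Problem sizes

The test suite runs its Monte Carlo checks at 1.5×10⁴–10⁵ histories per
configuration; the acceptance script (`scripts/acceptance.R`) uses 2×10⁵
histories per configuration for spot-size and transmission sweeps and
5×10⁵ for the peak-to-entrance comparisons. At these sizes the MC noise on
a spot σ is well below 2% and on a transmission fraction below 0.005.

## Known limitations

* High-Z stopping powers from the uncorrected Bethe formula carry a
  few-percent systematic; the tungsten stopping-thickness comes out ~1%
  above the 11.1 mm reference design value.
* The maximum beamlet transmission (largest bore, deepest peak) is set
  almost entirely by the in-air spot σ at the deepest study energy; with
  the two-anchor 1/E beam model (σ ≈ 2.9 mm at 140 MeV) it reaches ≈ 0.59,
  whereas a machine with σ ≈ 2.6 mm there would reach ≈ 0.7.
* Gaussian straggling and the removal-only nuclear model idealize the
  distal falloff and the dose halo; quantities dominated by the nuclear
  halo are approximate.
* The relative entrance-LET ordering between tungsten and nickel apertures
  differs by only a few percent and is sensitive to the simplified
  slit-scattering physics; entrance-LET conclusions should not be drawn
  from this model.
* Paraxial slopes, no δ-ray transport, no patient heterogeneity, no beam
  optics.
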
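---
title: "Evaluating nanoparticle dose enhancement under kilovoltage X-rays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating nanoparticle dose enhancement under kilovoltage X-rays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npdef)
```

## The problem

High atomic number (high-Z) nanoparticles suspended in tumour tissue absorb
kilovoltage X-rays far more strongly than water, locally boosting the
absorbed dose. How large that boost is depends sensitively on the photon
spectrum: tube voltage, anode material and filtration move the photon
energies relative to the photoelectric absorption of the nanoparticle
material, and the beam hardens further as it penetrates tissue. `npdef`
evaluates this macroscopic dose enhancement analytically, for eleven metal
and metal-oxide nanoparticle compositions (Cu, ZrO2, Ag, CeO2, Gd2O3, Tm2O3,
HfO2, Ta2O5, Bi2O3, Pt, Au) across libraries of tube spectra from 30 to
300 kVp.

## The model

The dose enhancement factor (DEF) is the dose absorbed in the volume of
interest with nanoparticles present divided by the dose absorbed there
without them. Under charged-particle (electronic) equilibrium, dose equals
collision kerma, so for a monochromatic beam of energy $E$

$$\mathrm{DEF}(E) =
  \frac{(\mu_{en}/\rho)_{\mathrm{mix}}(E)}{(\mu_{en}/\rho)_{\mathrm{w}}(E)},$$

and for a binned photon spectrum $N_i$ at energies $E_i$

$$\mathrm{DEF} =
  \frac{\sum_i N_i E_i\,(\mu_{en}/\rho)_{\mathrm{mix}}(E_i)}
       {\sum_i N_i E_i\,(\mu_{en}/\rho)_{\mathrm{w}}(E_i)}.$$

The loaded medium is water with $c$ mg of nanoparticle material added per mL
of water, giving a nanoparticle mass fraction $w_{NP} = c/(c+1000)$
(`np_loaded_water()`; the alternative convention, per mL of final
suspension, differs by under 0.01% at the default 10 mg/mL and is not
implemented). Compound coefficients follow the elemental mixture rule
$(\mu/\rho)_{\mathrm{mix}} = \sum_i w_i (\mu/\rho)_i$. Because the mixture
rule is affine in the mass fractions, $\mathrm{DEF}-1$ is exactly
proportional to $w_{NP}$ at fixed spectrum — a property the test suite
exploits.

Electronic equilibrium is an approximation: for monochromatic kilovoltage
beams and small scoring volumes it bounds the dose error at roughly 10%, and
it ignores the nanoscale dose inhomogeneity around individual particles.
The package therefore predicts *macroscopic* enhancement only, not
microdosimetric or biological effect.

## Coefficient tables

`inst/extdata/photon_coeffs/` ships one plain-text table per element
(27 elements: H, O, the Be window, the filter set, and the nanoparticle
constituents), each holding total mass attenuation $\mu/\rho$ (coherent
scattering included) and mass energy-absorption $\mu_{en}/\rho$ on a 1–300
keV grid, with duplicated rows at absorption edges. The tables for H, O and
Al are transcriptions of the standard reference grids (O is recovered from
the reference water table through the mixture rule, so that dosimetric
water, $\{H: 0.1119, O: 0.8881\}$, reproduces the published water
coefficients essentially exactly). The remaining 24 elements are computed by
the generator in `tools/make_photon_tables.py` from a physical model:
Cromer–Liberman photoabsorption, Klein–Nishina incoherent scattering with a
Thomas–Fermi-scaled incoherent-scattering-function correction, form-factor
coherent scattering, and a shell-resolved fluorescence-escape model for
$\mu_{en}$. Against reference anchor values (water, Al, Cu, W, Au, Pb) the
computed tables agree to about ±2.5% below 150 keV; they are a re-tabulation
of that quality, not a copy of a published file. This accuracy is ample for
spectrum-weighted DEF (the headline gold maximum is reproduced within a few
percent) but it limits *differences between neighbouring elements*: the
package reports Pt/Au and HfO2/Ta2O5 average-DEF gaps of about 0.01, at the
edge of what the per-element relative accuracy can resolve.

Interpolation between grid points is log–log linear — the standard scheme
for photon coefficient data, exact on power-law segments and therefore exact
at grid points. At a duplicated edge energy a query resolves to the
higher-energy branch. Queries outside 1–300 keV raise an error rather than
extrapolate, since the study never needs them.

## Beam quality and depth

A spectrum is a photon-count histogram on a uniform 0.5 keV grid of bin
centres. Three metrics characterise it:

* **Average energy** — the fluence-weighted mean $\sum N_i E_i/\sum N_i$
  (chosen over energy-fluence weighting; the convention is stated because
  the quantity is reported but not defined in many tabulations).
* **Aluminium half-value layer (HVL)** — the thickness halving the
  transmitted *energy fluence*, found by bracketing bisection on
  $[0, 200]$ mm to an interval below $10^{-9}$ mm, with
  $\rho_{Al} = 2.699$ g/cm³ and total attenuation including coherent
  scattering.
* **Effective energy** — the energy of the monoenergetic beam with the same
  aluminium HVL, obtained by inverting $\ln 2/\mu_{Al}(E)$ on the
  monotone-decreasing branch above 2 keV (the aluminium K edge at 1.56 keV
  bounds it from below).

Depth attenuation in water multiplies each bin by
$\exp(-k(E_i)\rho_w d)$. Following the study's analytical formulation, the
default coefficient $k$ is the water *energy-absorption* coefficient; this
is physically non-standard (narrow-beam attenuation uses total $\mu$), so a
`mode = "total_attenuation"` switch is provided and the choice is recorded
in the spectrum metadata. One observable consequence of the default rule:
water's $\mu_{en}/\rho$ has its minimum near 100 keV and rises toward
300 keV, so beams with effective energy above ~100 keV *soften* marginally
(by under 0.05 keV) with depth under this rule, while true attenuation
hardens every beam. The hardening invariant is accordingly tested under
total attenuation, and under the default rule for beams in the kilovoltage
working range (effective energy below 80 keV), where both modes harden.

## The synthetic spectrum library

The reference spectrum set that the survey emulates is a collection of 237
Monte-Carlo tube spectra (30–300 kVp; W, Mo and Rh anodes at roughly
82/12/6%; beryllium window; filter stacks drawn from Al, Cu, Pd, Mo, Rh, Ba,
Sb, V, Mn, Fe, Ni, Zr, Sn, Pb and water). The individual stack compositions
of that set are not available, so `generate_library()` reproduces its
*statistical* structure rather than its members:

* a thin-target Kramers continuum, $N(E) \propto Z\,(U-E)/E$ on the 0.5 keV
  grid from 1 keV to the tube voltage — it captures the degrees of freedom
  that drive DEF (voltage, filtration, anode lines) at desk scale, which is
  why it stands in for full electron-photon Monte-Carlo transport;
* characteristic K and L anode lines added into the nearest bins when the
  tube voltage exceeds the excitation edge, with total line content a
  configurable fraction (default 0.10) of the above-edge continuum counts —
  a shape heuristic, not a fluorescence model;
* a fixed 0.005 mm anode-material filter approximating target
  self-absorption, and a 2 mm Be window (3 mm for the therapy presets);
* per spectrum, 0–3 random filter layers, materials uniform over the list
  above, thicknesses log-uniform over clinical ranges (Al 0.5–5 mm,
  Cu 0.05–3 mm, Sn/Pb 0.1–5 mm, others 0.05–1 mm);
* voltages recycled over 30–300 kVp in 10 kVp steps; anodes apportioned to
  the configured mix by largest remainder; everything driven by one seed,
  so a library is exactly reproducible.

A sampled stack that transmits less than $10^{-6}$ of the unfiltered counts
(for example millimetres of lead on a 30 kVp beam) is redrawn: such a beam
has effectively no photons, violates the usable-spectrum invariant, and
would not appear in any tube data set. The generated libraries span light
filtration (effective energy well below half the voltage) to very heavy
filtration (effective energy approaching the voltage), matching the spread
of the reference set.

What the generator does *not* emulate: electron transport in the anode
(real continua are not exactly Kramers-shaped), off-axis heel effects,
detector response, or any specific commercial tube. Survey conclusions that
depend only on spectrum-shape degrees of freedom (which beam qualities
enhance which materials) transfer to real spectra; absolute percentages of
"spectra above a DEF threshold" depend on the sampled stack mix and should
be read as representative, not exact.

## The survey and its summaries

`def_survey()` evaluates the full (spectrum × material × depth)
cross-product; records key each DEF to the *initial* spectrum's voltage and
effective energy, so depth series stay comparable on fixed beam-quality
axes. Summaries reproduce the reference analyses: min/average/max per
material and depth, counts per DEF class (left-closed bins
$<1.2, [1.2,1.4), \dots, \ge 2.2$; the boundary convention is stated
because printed ranges leave it ambiguous), pairwise dominance (strict
inequality, ties to neither side), and the high-DEF region — the bounding
box in (voltage, effective energy) of all cells at or above a threshold,
default 2.3, which outlines the most beneficial beam-quality region for
gold at 10 mg/mL.

Averages weight all spectra equally (the alternative — grouping by voltage
first — is not used; with voltages recycled uniformly the two nearly
coincide).

## The spherical-tumour scenario

`build_scene()` places a sphere of nanoparticle-loaded water (default
radius 1 cm — a 2 cm diameter tumour; the alternative 2 cm radius reading
of the source geometry is available through the `radius` argument) at 1 or
3 cm depth in a 20 cm water phantom, irradiated by a parallel circular
field (default 4 cm diameter; no field size or source distance is specified
in the reference scenario, so a parallel beam with no inverse-square falloff
is the modelling choice). Dose is scored on a cylindrical (r, z) grid with
1 mm steps.

Transport is primary-photon only and scatter-free: along each voxel column
the spectrum is attenuated with total $\mu$ through the media traversed
(water, and tumour material where the column crosses the sphere, density
$(1000+c)/1000$ g/cm³), and the energy fluence lost in a voxel deposits
locally in proportion to the local $\mu_{en}/\mu$. This formulation makes
the transport loop exactly energy-conserving — with $\mu_{en}$ set equal to
$\mu$, the energy removed from the beam equals the energy deposited along
the path to floating-point accuracy, which the test suite verifies on toy
power-law tables. Because scattered photons and buildup are omitted,
absolute in-tumour DEF values from scatter-inclusive Monte-Carlo are *not*
reproduced; the scenario supports qualitative orderings only (the 200 kVp
preset yields a lower in-tumour maximum than the 120 and 180 kVp presets;
moving the tumour from 1 to 3 cm depth shrinks the DEF spread; the upstream
pole always sees at least the enhancement of the downstream pole; the dose
immediately behind a gold-loaded tumour drops by roughly 20%).

The four preset beams (`preset_beams()`) use the reference filtrations —
120 kVp (0.5 mm Al + 0.1 mm Cu), 180 kVp (1.5 mm Al + 0.15 mm Cu), 200 kVp
(1.0 mm Al + 0.5 mm Cu), 300 kVp (1.5 mm Al + 0.25 mm Cu), W anode, 3 mm
Be. Their HVLs are reported as a calibration diagnostic next to the nominal
clinical values, not asserted: a Kramers continuum is somewhat harder than
a real tube spectrum at equal voltage and filtration.

## Numerical choices

* Bisection for the HVL runs to an interval of $10^{-9}$ mm (about 50
  iterations), so monochromatic HVLs match the closed form
  $\ln 2/\mu_{Al}(E)$ to well below $10^{-5}$ relative even for soft beams.
* Effective-energy inversion uses `uniroot` at $10^{-6}$ keV tolerance on
  [2, 300] keV; an HVL outside the invertible range raises an error.
* Spectrum files are written with 17 significant digits, so a write/read
  round trip is bit-exact; on reading, counts below $10^{-12}$ of the
  maximum are zeroed to keep HVL brackets stable, and 1 keV grids are split
  into half-count 0.5 keV bins (count-preserving) with a warning.
* All randomness flows through one seed; `generate_library()` and
  `run_full_study()` are byte-reproducible given it.
* Degenerate inputs raise errors rather than guess: all-zero spectra,
  negative depths or concentrations, non-uniform grids, compositions that
  do not sum to one, tumours protruding from the phantom.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the survey at its full size
— 237 spectra × 11 materials × 2 depths — because the analytical pipeline
is cheap (a few seconds); the stochastic property suite uses a 100-spectrum
library, and tumour maps use the full 1 mm grid. Nothing is scaled down
from the reference study except the number of depths surveyed by default.

## Known limitations

* Coefficient tables are a few-percent re-tabulation; comparisons *between
  neighbouring elements* (Pt vs Au, HfO2 vs Ta2O5) inherit that relative
  error, and their near-equality is asserted only loosely (gap < 0.05).
* The Kramers continuum over-weights the high-energy end of real tube
  spectra slightly; library-average DEFs run a few percent below the
  reference values while maxima and orderings agree.
* Printed effective atomic numbers in the reference material table are not
  reproducible from the Mayneord power mean (one exceeds the metal's own Z,
  which no electron-fraction-weighted mean can); `z_eff_mayneord()`
  implements the definition literally and treats those printed values as
  non-normative.
* No scatter, no secondary-electron transport, no microdosimetry, no
  biological endpoint.

## A worked example

```{r example, eval = FALSE}
library(npdef)
tables <- load_coefficients()
lib <- generate_library(library_config(n_spectra = 237, seed = 1), tables)
au <- np_loaded_water(from_formula("Au"), 10)
sv <- def_survey(lib, list(au), depths = c(0, 0.4), tables = tables)
summary(sv)
region <- high_def_region(sv[sv$depth == 0, ], threshold = 2.3)
region$voltage_range
region$effective_energy_range
```
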
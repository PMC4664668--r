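---
title: "Physics and conventions of the minibeamtx models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics and conventions of the minibeamtx models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibeamtx)
```

Minibeam radiation therapy delivers arrays of parallel beams a few tenths
of a millimetre wide. Normal tissue tolerates such spatially fractionated
dose far better than a solid field, while multiple Coulomb scattering
(MCS) gradually broadens the beams with depth until the array merges into
a solid field at the target. `minibeamtx` models that chain quantitatively
for protons, light ions and carbon: stopping and range, MCS broadening,
array dosimetry and merge depth, Bragg-peak spreading, and the geometry
and dose bookkeeping of interleaved carbon arrays. This vignette records
the physics choices and conventions, in the order a calculation uses them.

## Stopping power and range

Electronic stopping is the plain Bethe formula without shell or
density-effect corrections, which are sub-percent over the supported
window of 1–500 MeV per nucleon. Water is the reference medium (density
1 g/cm^3, mean excitation energy 75 eV, radiation length 36.08 g/cm^2);
other materials can be supplied with explicit constants. The CSDA range
is the trapezoidal quadrature of $a\,dE/S(E)$ on a 600-point log-spaced
energy grid from the 1-MeV/u cutoff (the residual range below the cutoff
is under 0.1 mm and is neglected). Forward and inverse range lookups are
cached monotone (Hyman) splines; `energy_for_range()` refines the inverse
with a root-finding pass so a round trip closes to better than 0.01 cm.

```{r}
p <- ion_species("proton")
csda_range(p, 109)          # cm in water
energy_for_range(p, 10)     # MeV/u for a 10-cm range
```

## Scattering model

Beam spreading uses Fermi–Eyges moment transport with a *differential*
Highland scattering power

$$T(z) = \left(\frac{14.1\,z_{\mathrm{ion}}}{p\beta c}\right)^{\!2}
  \frac{1}{X_0}\,f(L), \qquad
  f(L) = \left(1 + \tfrac{1}{9}\log_{10} \tfrac{L}{X_0}\right)^{2}
  \;\text{clamped to } [0.25, 1],$$

with $p\beta c$ the product for the whole ion at the local residual
energy and $L$ the cumulative water-equivalent thickness traversed so
far. Evaluating the logarithmic correction at the cumulative thickness
(rather than per step) keeps the integrated angular variance consistent
with the single-slab Highland formula while remaining a well-defined
local scattering power — which is what makes the same $T$ usable by both
the moment recursion and the Monte Carlo check below.

`propagate_moments()` advances the angular variance $A_0$, the
position–angle covariance $A_1$ and the positional variance $A_2$ with a
trapezoidal recursion, evaluating $T$ at the mid-step energy and
thickness. The lateral FWHM combines the incident width with the MCS
spread in quadrature (Gaussian incident profile) or by numerical
convolution (top-hat profile; the two differ by under 5% near merge
depths). Transport stops at 95% of the CSDA range: end-of-range
straggling and large-angle single scattering are outside the model, and
all higher-level functions respect the same limit.

`mc_transport()` is an independent condensed-history random walk: a
Gaussian angular kick of variance $T\,\Delta z$ followed by a drift, per
step. The kick-then-drift discretisation matches the trapezoidal moment
recursion to second order in the step, so the sampled FWHM tests the
moment bookkeeping rather than the shared discretisation error. It is
seed-reproducible and restores the caller's RNG state.

```{r}
b <- beam_spec("proton", 109, shape = "pencil", incident_width_fwhm = 0.3)
depth_for_width(b, 0.7)     # mm to broaden from 0.3 to 0.7 mm FWHM
```

A note on absolute scale: with this scattering power a 109-MeV proton
minibeam needs roughly 29 mm to reach 0.7-mm FWHM, whereas some published
film measurements and Monte Carlo studies of the same geometry quote
values around 23–24 mm. Pure-water MCS cross-checks (the Lynch–Dahl form,
and end-of-range spread benchmarks) agree with our curve to a few
percent, so we attribute the difference to unmodelled source terms in
those setups (collimator scatter and divergence). We deliberately do not
tune the scattering power to reproduce any particular measurement, since
a factor that fixes protons degrades carbon and vice versa.

## Arrays, PVDR and merge depth

`array_profile()` superposes Gaussian per-beam kernels on a comb (planar
sheets) or square lattice (pencils). Profiles are normalised so a single
beam's central-axis entrance dose is 1; the per-beam amplitude then
decays like the inverse (planar) or inverse-squared (pencil) width
ratio, which is just lateral redistribution — the period-averaged dose
is conserved. The peak-to-valley dose ratio (PVDR) is measured on the
three central periods to avoid edge effects.

Two operational merge-depth rules are computed by `merge_depth()`:

* **valley rule** (default): smallest depth where valley/peak reaches
  0.95;
* **FWHM rule**: depth where a single beam's FWHM equals the on-center
  spacing.

Both are reported; they agree to roughly 10% for the geometries here.

## Dose bookkeeping

The collimator yield is the geometric open fraction, `width/spacing` for
a multislit and $\pi (w/2)^2 / s^2$ for a pinhole lattice. Its
reciprocal is the incident-dose factor: how much larger the in-beam
entrance dose must be than a solid beam's for the same field-averaged
dose. Divided by the tissue-sparing factor (default 7, the ratio of
tolerated minibeam to solid-beam dose), it gives the estimated
*biological* entrance-dose ratio of the array. Reported values round
factors to one decimal and ratios to two — `dose_bookkeeping()` keeps
the exact values alongside the rounded report, and downstream use of the
quoted numbers (e.g. 2.3/7.0 = 0.33) starts from the rounded factor, the
same convention used when the numbers are quoted in print.

```{r}
dose_bookkeeping("planar", 0.3, 0.7)
```

## Bragg curves and SOBP

The pristine Bragg curve is the stopping power at the residual energy,
convolved with a Gaussian range-straggling kernel
($\sigma_R = 0.012\,R^{0.935}$ cm for protons, scaled by $1/\sqrt{a}$
for heavier ions); an explicit beam energy spread widens the kernel via
the range–energy slope. Nuclear fragmentation tails are not modelled,
which mainly affects carbon's entrance-to-peak ratio.

`build_sobp()` stacks layers whose *peak positions* (not CSDA ranges —
straggling pulls the observable peak about one $\sigma_R$ upstream)
span the plateau, and solves nonnegative least squares for the weights.
Flatness is `(max − min)/mean` over the plateau, with a 3% goal; if the
layer spacing is coarse relative to the straggled peak width (easy to
provoke with carbon, whose peaks are a few tenths of a millimetre wide)
the achieved flatness is reported with a warning rather than silently
accepted. The plateau mean is normalised to 1.

The photon comparison curve is a textbook 10-MV build-up-plus-exponential
model (maximum at 25 mm, effective attenuation 0.0045/mm).
`compose_depth_dose_comparison()` overlays photon, solid-ion SOBP and the
minibeam array's estimated biological dose: the entrance ratio applies
proximal to the merge depth and ramps linearly to 1 there (the endpoints
are the modelled quantities; the ramp shape is a presentation choice).

## Interleaved carbon arrays

`interleave_plan()` describes 2- or 4-directional interleaving in an
axial plane: opposing pairs enter along ±x and ±y, and within each
90° pair one array's planes are offset by **half the on-center spacing**
of the other, so the planes interleave at the target. Each array's energy
is set so its range equals the distance to the *distal* face of the
target box (the distal SOBP layer; shallower layers traverse the proximal
edge no wider). The reference geometry is a 6.5-mm target centred in a
78.5-mm phantom with 1.05-mm on-center spacing.

`check_coverage()` verifies the interleave contract at the
target-proximal edge: the beam FWHM there must reach the half-spacing
gap (within a 5% abutment tolerance — "abut" means the half-maximum
edges touch; more than 10% overlap is flagged as an over-dose seam) and
must not exceed the 0.7-mm width limit where the tissue-sparing effect
starts to fade. `max_proximal_depth()` inverts that limit: the largest
proximal-edge depth at which a beam whose range is the depth plus a
20-mm target-span margin still satisfies the width limit, re-choosing
the energy at each candidate depth.

In the composed map (`compose_interleaved_dose()`), doses of the two
arrays of a 90° pair do not add up outside the interleaved plateau —
pair members combine by per-voxel maximum — while inside the target each
pair deposits its SOBP plateau dose (pedestal × pedestal-to-SOBP ratio,
a plan input since it depends on the SOBP weighting) and pairs sum. The
GyE map is physical dose times a scalar RBE. The carbon incident-dose
factor pair combines the pair non-additivity factor 2 with broadening
dilution: the upper bound uses the maximal dilution `spacing/width`
(2 × 0.7/0.3 ≈ 4.7), the lower bound the dilution already realised at
the target, `2 × spacing/width_at_target` (equal to 2.0 when the beams
have broadened to the spacing). The lower-bound convention is ours; only
the construction of the upper bound is standard.

```{r, eval = FALSE}
plan <- interleave_plan("carbon12")
check_coverage(plan)
map <- compose_interleaved_dose(plan, lateral_res = 0.25)
map$report$target_physical_dose   # 40 Gy
map$report$target_gye             # 120 GyE at RBE 3
```

## Validity limits and problem sizes

* Energies 1–500 MeV/u; ranges 0.5–40 cm; transport to 95% of range.
* Default steps: 0.1 mm moment integration, 0.05 mm Monte Carlo,
  0.01 mm lateral profile grid, 0.05 mm × 0.5 mm interleave map.
* Everything runs in seconds on one CPU except the Monte Carlo oracle,
  which is about 10 s per 10^5 histories over a 40-mm track.

Out of scope: nuclear fragmentation, collimator optics and scatter,
end-of-range straggling in the lateral model, voxelised heterogeneous
anatomy, and any biological modelling beyond the scalar sparing factor
and RBE.
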
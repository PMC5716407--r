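---
title: "Correcting the LET dependence of MOSFET proton dosimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting the LET dependence of MOSFET proton dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosfetcf)
```

## The problem

MOSFET detectors are attractive for in vivo dosimetry in proton therapy:
they are millimetre-sized and easy to place. Their drawback is a strong
linear-energy-transfer (LET) dependence: as protons approach the end of
their range the LET rises steeply and the detector's sensitivity per unit
dose falls, so a raw MOSFET reading near or inside a spread-out Bragg peak
(SOBP) underestimates the dose by on the order of 15%, and by 27% at a
pristine Bragg peak.

`mosfetcf` implements the correction strategy of computing, at any point
of interest, *two* transport solutions from the same beam model: one driven
by the ionization-chamber depth-dose curve DD(z) ("what the dose is") and
one driven by the MOSFET depth-output curve DO(z) ("what the detector
reads"). Their ratio at the point is the correction factor

CF(x, y, z) = D_dose(x, y, z) / D_output(x, y, z),

and the corrected measurement is CF times the raw MOSFET dose (reading in
mV times the calibration factor in cGy/mV). Two engines are provided:

* a **simplified Monte Carlo (SMC)**: per-proton tracking on a voxel
  raster of relative stopping power (RSP), with energy loss taken from the
  measured curves through the water-equivalent model and multiple Coulomb
  scattering sampled from the Highland formula;
* a **pencil-beam algorithm (PBA)**: deterministic superposition of
  pencils, each evaluating the broad-beam curves at the water-equivalent
  depth along its own straight axis with a single lateral Gaussian.

The PBA samples heterogeneity only on each pencil's axis, so behind
lateral density gradients (bone edges, air cavities) the two engines
separate; the SMC is the reference and the PBA the comparator, which is
exactly the situation the correction method is designed to expose.

## Curve models

**Pristine Bragg curve.** The per-particle ("ideal") depth-dose is the
exact cell average of the Bethe stopping power along the range-energy
relation (I = 75 eV for water; no shell or Barkas corrections, adequate to
about 1% against standard tabulations at 30-250 MeV). The broad-beam
("measured") curve is its convolution with a Gaussian range-straggling
kernel, sigma = 0.012 R^0.935 (R in cm; about 2.4 mm at R = 239 mm).
Both tabulations are kept on a 0.5 mm grid, the curve is shifted so its
distal-80% depth equals the requested clinical range, and normalized to 1
at the entrance. Keeping the ideal/measured pair explicit is what lets
the Monte Carlo be exactly self-consistent (next section).

**SOBP.** A ridge filter is a set of upstream absorber steps, i.e. range
shifts: the SOBP is a weighted sum of range-shifted copies of the pristine
curve at 2.5 mm spacing. Non-negative weights come from a Lawson-Hanson
least-squares fit to a flat target over the modulated region excluding the
distal 3 mm (the intrinsic distal falloff of the deepest component cannot
be flattened); achieved flatness is verified to +/-2% and a failure is an
error, not a warning.

**Detector response.** The MOSFET's relative sensitivity is modelled as a
function of *residual range* r (mm of water) rather than depth:
s(r) = 1 for r >= r0, and 1 - a (1 - r/r0)^b below, with r0 = 30 mm and
b = 2. Residual range is the physically meaningful variable (it is in
one-to-one correspondence with energy, hence LET), so a single calibration
transfers from the pristine geometry to SOBP and heterogeneous cases. The
amplitude `a` is calibrated in closed form so that the *measured* 190 MeV
fixture exhibits an output/dose ratio of exactly 0.73 at the Bragg-peak
depth and 1.0 at the entrance. The depth-output curve is built by
weighting the ideal curve by s and convolving afterwards - the order
matters at the few-percent level near the peak, and this order is the one
the per-particle Monte Carlo realizes.

## The SMC and its self-consistency

Each proton carries position, direction and residual range. Per geometric
step ds the water-equivalent loss is dwed = RSP x ds; the proton deposits
`DD_ideal(Z - r)` x dwed (and `DO_ideal(Z - r)` x dwed on the paired
output grid), where Z is the nominal range of the curve pair - so a proton
at residual range r reads the curve at the water-equivalent depth it would
have in water. Scattering adds two Gaussian projection angles per step
with the Highland sigma, using X0(water)/RSP as the local radiation
length. Tracking ends at r = 0 (with an exact partial step) or at the
phantom boundary (protons leaving laterally are dropped).

Per-proton randomness enters the source: positions from the fluence
profile inside a hard circular aperture blurred by a 2 mm effective-source
spot; slopes with the 4 mrad angular sigma of the effective source model;
a ridge-filter component sampled from the SOBP weights; and a residual
range offset from the straggling Gaussian. The last two are the crucial
design choice: **every proton deposits the sharp per-particle curve, and
the sampled range spread reconstructs the measured curve in aggregate.**
Giving all protons the nominal range and the measured curve instead (the
naive reading) truncates the distal falloff - protons all stop at the same
depth, and the scored dose at the distal-80% point comes out ~34% low -
and makes an SOBP sag several percent toward its distal end. With the
pair construction the central-axis dose in water reproduces the measured
curve to better than 1% through the SOBP and the peak.

Known residual: the SMC accumulates depth along the scattered *path*, so
its distal edge sits about 0.5-0.7 mm proximal to the analytic curve
(which is built in the CSDA sense). This is invisible below 90% of the
range, cancels exactly in all correction-factor ratios, and is the reason
self-consistency checks are specified for depths < 0.9 R.

Scoring uses the phantom grid downsampled 2x in-plane ("2-pixel"
calculation grid; 1.172 mm at the CT raster default of
0.586 x 0.586 x 3 mm) and a step of min(1 mm, half the smallest voxel
dimension). Both grids are scored from the same trajectories (paired
scoring), which makes CF >= 1 hold voxel-by-voxel for any sensitivity
<= 1 and suppresses CF variance. Statistical uncertainty uses the batch
method (10 batches, each re-seeded from a master seed, so runs are
bit-reproducible); the per-voxel relative standard error is summarized as
a root-mean-square over a region. Grids are normalized so the dose at the
prescription point (the isocenter) is 100 cGy per fraction.

## The PBA

A pencil at entrance (x0, y0) contributes
phi DD(z_wed) exp(-rho^2 / 2 sigma(z)^2) / (2 pi sigma(z)^2), with z_wed
the water-equivalent depth (plus range-shifter) along *its own* axis.
sigma(z)^2 adds in quadrature: the entrance spot (2 mm), the angular sigma
times the travelled distance, and the Fermi-Eyges accumulation
int T(u) (z-u)^2 du of the Highland scattering power along the axis.
Pencils sit on a 2 mm grid inside the aperture; in laterally homogeneous
media the superposition reproduces the broad-beam curve to quadrature
accuracy (measured: < 0.1% on the axis), and a spacing coarser than the
entrance sigma triggers a ripple warning. The PBA uses the *measured*
broad-beam curves directly - for an SOBP, the component-wise output curve
described above - which keeps its correction factors consistent with the
SMC's in water to within 2%.

## Synthetic fixtures: the stated world

No measured inputs ship with the package; the fixtures emulate the
experiment the method was designed for:

* a 190 MeV beam, clinical range 239 mm, with a 0.73 peak output/dose
  anchor for the response calibration;
* a 50 mm SOBP, 7.5 mm range shifter, 15 mm aperture radius;
* a MOSFET calibrated by five 200 cGy exposures at 157 MeV / 0.5 keV/um
  (a plateau geometry: LET low enough that no response correction is
  needed at calibration);
* a head-like voxel phantom (160 x 160 x 90 voxels at the CT raster): a
  soft-tissue block with a cortical-bone jaw arc (RSP 1.6), an air oral
  cavity (RSP 0.001, a 12 mm sphere) and a lateral half-field bone plate
  whose edge crosses the beam - deterministic per seed, with insert
  positions jittered by the seed;
* seven measurement points A-G in and around the SOBP target, of which at
  least two sit in steep-gradient regions (the distal edge and the plate
  edge), and two are shadowed by the air cavity - reproducing the
  qualitative pattern that some in vivo points show the full ~15% raw
  underestimation while shadowed ones show almost none;
* a prescription of 100 cGy per fraction at the isocenter, three
  fractions, and simulated readings with 1.5% multiplicative
  reproducibility noise.

The packaged history count (2,000,000 in 10 batches) was chosen once so
that the mean statistical error over the >= 90%-of-prescription target
region of this fixture is <= 2% rms (measured 1.95-1.97% across seeds);
error scales as 1/sqrt(N) if you change it.

What the generator does *not* emulate: nuclear interactions and their
~1%/cm fluence loss (implicitly absent from both the synthetic curves and
the transport, so the pair stays consistent); a nuclear-halo second
Gaussian in the PBA kernel; detector angular or temperature dependence;
energy spread beyond Gaussian range straggling; and any feature of the
real anthropomorphic phantom's anatomy. A green test therefore
establishes internal consistency of the method chain - curve models,
transport, correction, uncertainty - on a stated world, not agreement
with any clinical measurement.

## Uncertainty model

Error bars on a corrected point dose combine, in quadrature:

* **setup uncertainty**: the extreme deviation of the trilinearly
  interpolated dose over a 5 mm-diameter sphere around the point (sampled
  on a 0.25 mm lattice), modelling detector placement uncertainty - in
  steep gradients (> 5%/mm) this alone exceeds 12.5%;
* **statistical error**: the batch standard error of every stochastic
  grid entering the estimate (truth and engine, dose and output).

## Numerical choices and degenerate inputs

* Curve lookup is linear interpolation; before the first knot the first
  value is used, beyond the last knot the value is 0 (the beam has
  stopped). Curves are resampled to a 0.25 mm uniform table inside the
  engines.
* Trilinear interpolation reads points off grids; out-of-field points
  (output below 1% of maximum) are errors for correction factors and
  flagged rows in experiment tables.
* A zero-width SOBP degenerates to the single pristine peak; a width that
  cannot reach the flatness tolerance at the chosen spacing is an error
  naming the achieved flatness.
* Voxels own the half-open cube centred on their centre; positions are in
  mm with the beam along +z and the entrance face at z = 0.
* The HU-to-RSP calibration is a five-point monotone table anchored at
  HU 0 = water; it is a documented stand-in, since clinical calibrations
  are scanner-specific.
* Polyethylene's RSP is pinned to the operational value 1.02 so
  water-equivalent conversions are bit-reproducible rather than derived
  from composition.

## Worked example

```{r example, eval = FALSE}
library(mosfetcf)

fx <- fixture_curves_190(sobp_width = 50)   # curves + calibrated response
beam <- fixture_beam_190()                  # 190 MeV, 50 mm SOBP, 7.5 mm shifter
phantom <- make_head_like(seed = 7)

grids <- run_smc(phantom, beam, fx$pristine_dd, fx$pristine_do,
                 n = smc_default_histories(), seed = 7, batches = 10,
                 prescription = list(point = c(0, 0, 206.5), dose = 100))

p <- c(5, 0, 218.5)                         # a point in the SOBP
cf <- cf_smc(grids$ppic, grids$mosfet, p)
rec <- calibrate(rep(400, 5), delivered_cGy = 200)
raw <- raw_dose(simulate_measurement(grids$mosfet, p, rec), rec)
cf * raw                                    # corrected dose, cGy
```

## Limitations

* The SMC distal edge is ~0.5-0.7 mm proximal to the analytic curves
  (path-detour vs CSDA); ratios are unaffected.
* The PBA carries a single Gaussian kernel; large-angle and nuclear-halo
  tails are out of scope, so its absolute penumbra is idealized.
* The legacy depth-based correction is provided for comparison only; it
  is exact in laterally homogeneous media and degrades behind
  heterogeneity by construction.
* Reported in-phantom numbers from any specific clinical setup are not
  reproduction targets: the real phantom CT, beamline and planning data
  are unpublished, and the head-like fixture is an analogue.
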
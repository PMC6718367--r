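---
title: "Modeling head scatter with an explicit MLC scatter source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling head scatter with an explicit MLC scatter source}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcscatter)
```

## The problem

The in-air output ratio $S_c$ of a linac photon beam is the ratio of the
primary-beam output (collision kerma in a miniphantom) for a given
collimator setting to that at the reference 10 × 10 cm² setting.  Accurate
$S_c$ values per segment are the backbone of independent monitor-unit
checks for IMRT and VMAT plans, which contain many segments whose
calculation point is partly or fully blocked by multi-leaf collimator
(MLC) leaves.

The conventional dual-source model (DSM) treats the head as a focal point
source plus an extra-focal Gaussian source at the flattening filter, with
a monitor-backscatter correction.  The MLC enters only as a blocker of the
detector's eye view (DEV).  That ignores radiation *scattered by the
leaves themselves*, which biases $S_c$ for MLC-defined fields by up to
about a percent — small per segment, but systematic across the dozens of
blocked segments in a modulated plan.

This package implements the dual-source model together with an explicit
MLC scatter source located at the mid-MLC plane, and the machinery around
it: exact rectilinear aperture geometry, constrained least-squares
calibration from measured-$S_c$ tables, Clarkson sector integration for
point dose in irregular fields, and a synthetic measurement-campaign
generator so the whole pipeline runs and is tested without any external
dataset.

## Dual-source model

For a field $fs$,

$$S_{c,DSM}(fs) = \frac{\bigl(1 + F_{efs}(fs)\bigr)\bigl(1 - F_{mbs}(fs)\bigr)}
  {\bigl(1 + F_{efs}(fs_{ref})\bigr)\bigl(1 - F_{mbs}(fs_{ref})\bigr)},$$

where $F_{efs}$ is the extra-focal scatter-to-primary ratio and $F_{mbs}$
the monitor-backscatter deficit.  $F_{efs}$ is the mass of a radially
symmetric bivariate Gaussian (width `sigma_ff`, amplitude `k_ff`) over
the DEV: the region of the extra-focal plane visible from the on-axis
detector through every collimator opening.  Each opening is
back-projected to the extra-focal plane with magnification
$(d_c/SAD)\,(SAD - d_{ff})/(SAD - d_c)$ for a collimator at distance
$d_c$.  Because every aperture decomposes into axis-aligned rectangles
(one x interval per leaf-pair strip — "slab form"), the Gaussian mass is
evaluated *exactly* as products of one-dimensional normal CDF
differences; no quadrature grid is involved.  $F_{mbs} = k_b\,(A_{max} -
A_{jaw})$ is linear in the blocked jaw area with $A_{max} = 1600$ cm²,
the minimal parameterization identifiable from a square/rectangle jaw
campaign.

The three parameters are fitted to jaw-only (MLC-retracted) measurements
by bounded Levenberg–Marquardt least squares on the $\chi^2$ objective
$\sum\bigl((S_{c,calc} - S_{c,meas})/SD\bigr)^2$, capped at 400
iterations with function tolerance $10^{-6}$.

The shipped `reference_dsm_params()` (`k_ff` = 0.05, `sigma_ff` = 1.5 cm,
`k_b` = 6×10⁻⁶ per cm², extra-focal plane at 12.5 cm) are *synthetic
defaults*: they produce a realistic 6 MV $S_c$ range of roughly 0.97 at
4 × 4 cm² to 1.02 at 40 × 40 cm² and serve as the truth set of the
campaign generator.  They are not a calibration of any physical machine;
any real application must re-fit them to its own campaign.

## The scatter interface

The MLC scatter source distinguishes leaf structure that perturbs the DEV
from structure that merely sits in the beam.  The border is the *scatter
interface*: the jaw-defined field projected to the mid-MLC plane
(SMD = 51 cm) and scaled about the beam axis by

$$\alpha = \frac{SCD_x\,(SAD - SMD)}{SMD\,(SAD - SCD_x)} = 0.577$$

for the default geometry.  The jaw plane distance $SCD_x$ is not usually
quoted for a machine, so the default configuration fixes $\alpha = 0.577$
and derives $SCD_x = \alpha\,SMD\,SAD/(SAD - SMD + \alpha\,SMD) =
37.52$ cm by the closed-form inversion; either quantity may be given in
the machine config, never both.  One $\alpha$ serves both axes by
default; a per-axis value via `scd_y` is supported but off by default,
mirroring the single-coefficient definition above.

Fields classify into three categories:

1. leaves retracted clear of the jaw beam's-eye view — no MLC scatter,
   $S_{c,MLC} = 1$ exactly;
2. leaves shape the field but its boundary stays outside the interface;
3. the field boundary enters the interface (and hence the DEV).

A leaf tip sitting *exactly* on the jaw edge is classified category 2,
not 1: a rounded leaf end on the field border is irradiated and
scatters.  This tie-break also keeps the MLC-square series at a fixed jaw
monotone up to the jaw size.

## The MLC scatter source

The correction multiplies the dual-source value, $S_c = S_{c,DSM}\cdot
S_{c,MLC}$, and factorizes into a line-based and an area-based component,
$S_{c,MLC} = S_{c,line}\cdot S_{c,area}$, each split by the interface:

$$S_{c,MLC} = \Bigl\{ES_{line,out}(FP_{out})\,ES_{line,in}(FP_{in})\Bigr\}
  \cdot \Bigl\{ES_{area,out}(MA_{out} - RA_{out})\,
               ES_{area,in}(MA_{in} - RA_{in})\Bigr\}$$

with

$$ES_{line} = a\,(FP^b - RP^b) + 1, \qquad
  ES_{area} = e^{-(MA - RA)/2\sigma^2}.$$

$FP$ is the perimeter of the MLC-defined field and $RP$ the interface
perimeter (cm at the mid-MLC plane); $MA$ is the radiation-exposed leaf
area (jaw area minus MLC field area) and $RA$ its reference — the
interface area for the out region, and 3 × 3 cm² at the isocenter,
projected to the mid-MLC plane by $(SMD/SAD)^2$, for the in region, so
that every area in the formula lives in one plane.  The line factor grows
with the field perimeter (more rounded leaf ends exposed); the area
factor grows as the exposed leaf area shrinks.  $ES_{area} > 1$ when
$MA < RA$ is permitted.

Conventions the formulas do not pin down, and the choices made:

* **Perimeter split.**  Boundary segments are clipped against the
  interface rectangle; pieces lying exactly on its edge count as *in*
  (deterministic inward tie-break).  The split conserves totals exactly
  ($FP_{in} + FP_{out}$ equals the full perimeter, likewise areas); the
  tie-break does mean $S_{c,MLC}$ makes a small jump (order $a\,L^b$ for
  an edge of length $L$, about 1.5×10⁻³ here) at the instant a leaf-tip
  edge crosses the interface border.
* **Zero-perimeter regions.**  A field entirely inside the interface has
  $FP_{out} = 0$; the out line factor is then evaluated as written,
  $1 - a_{out}RP^{b_{out}}$, rather than forced to 1.  The alternative is
  available via `line_zero_fp_is_identity` in `sc_mlc()`.
* **Closed leaf pairs.**  Gap below `gap_tol` (0.05 cm at isocenter):
  no aperture contribution and the abutment line carries no perimeter.
* **Category 1** short-circuits to exactly 1, independent of parameters.

## Parameter model in the AP ratio

The six parameters $(a, b, \sigma)_{out/in}$ vary with the jaw setting.
The shipped reference calibration (`reference_mlc_params()`) tabulates
them for square jaws of 10, 20 and 30 cm — area-to-perimeter (AP) ratios
2.5, 5 and 7.5 — and `reference_apratio_model()` interpolates each as a
quadratic in the AP ratio.  $a$ and $b$ are interpolated on the linear
scale; $\sigma$, which climbs from ~18 to ~403 cm across that range, on
the **log scale**: a linear-scale quadratic through those three values
dips negative near AP ratio 3.75 (a 15 × 15 jaw) and cannot serve as an
interpolant, whereas $\log\sigma$ is nearly affine in the AP ratio.  The
per-parameter scale is recorded in the model object and in parameter
files, so fitted calibrations are self-describing.

The originally published quadratic coefficients are kept in
`reference_apratio_coefficients()` for reference.  Only their $a_{out}$
line is consistent with the per-jaw table (it reproduces 0.016 and 0.017
at AP ratios 5 and 7.5 after rounding); the published $\sigma_{out}$
line is negative over the whole fitted range and the remaining lines do
not reproduce the table, so tests pin only $a_{out}$ and the usable
interpolant is the log-scale model above.

Per-jaw fitted parameters always take precedence over the AP-ratio model;
the model is the interpolation fallback for unseen jaw settings, with a
warning outside the fitted range [2.5, 7.5].

## Fitting the MLC source

Stage 1 fits, per square jaw setting, all six parameters to the residual
ratio $S_{c,meas}/S_{c,DSM}$ over that jaw's MLC-square series
(categories 2 and 3 must both be present), with the same optimizer
controls as the DSM stage; $\sigma$ is optimized on the log scale for
conditioning.  Stage 2 fits the quadratic AP-ratio model through the
per-jaw results.

The optimizer warm-starts from the shipped reference calibration unless a
start is supplied.  That matters for the 10 × 10 jaw series: only the
4 and 5 cm squares fall inside its scatter interface, so the in-region
triplet is under-determined from that series alone and a cold start can
land anywhere on the flat manifold; the test suite demonstrates genuine
basin convergence from deliberately perturbed starts on the 20 and 30 cm
series, where both categories are well populated.  A series with fewer
rows than parameters is not fitted; the start values are kept and flagged
unconverged.

## Clarkson dose module

For point dose in irregular fields, the phantom scatter factor $S_p$ and
tissue maximum ratio TMR are sector averages of radial lookup tables:
one ray per angular sector (1° default, sampled at the sector center)
from the calculation point to the *first* aperture boundary crossing —
the primary-aperture convention; corridors of a non-convex maze beyond
the first wall are ignored, a documented limitation.  Dose is the factor
chain $D = MU \cdot k_{cal} \cdot S_c \cdot S_p \cdot TMR$.  The shipped
`synthetic_radial_tables()` are smooth monotone curves with plausible
shapes (saturating scatter build-up in radius, exponential attenuation
beyond build-up depth) for testing only; they match no machine's beam
data, and real use requires measured tables.

## The synthetic campaign generator

`campaign_design()` reproduces the standard modeling design: jaw squares
4–40 cm in 1 cm steps plus rectangles with one pair fixed at 4, 10 or
40 cm (dual-source stage, MLC retracted); centered MLC-square series
from 4 × 4 cm² up to the jaw size for square jaws of 10, 15, 20, 25 and
30 cm; and cross / mirrored-E / maze leaf templates at jaws 15, 20 and
25 cm.  `simulate_campaign()` evaluates the forward model and applies
multiplicative Gaussian reading noise, default relative SD 0.2% — the
repeat-reading SD bound of a careful $S_c$ campaign — with the SD column
carrying `noise_sd * Sc`.

The generator's truth is the shipped reference calibration plus the
synthetic dual-source defaults, with jaw 15/25 truth lying on the
AP-ratio interpolant by construction.  What the generator emulates:
the measurement design, the noise magnitude, leaf-width quantization of
MLC-defined fields (odd squares above 20 cm round out to the 1 cm outer
leaves).  What it does not: detector volume averaging, miniphantom
scatter, output drift, source-obscuring for sub-4-cm fields, leaf
transmission and tongue-and-groove.  Passing recovery tests therefore
demonstrates the correctness and identifiability of the *implementation*,
not agreement with any physical machine.

The irregular templates are versioned approximations (v1): published
leaf-by-leaf coordinates for the classic verification shapes do not
exist.  Each band opens a single leaf interval; the maze deliberately
blocks the beam axis — the motivating scenario for an MLC scatter term.

## Numerical choices

* Slab-form geometry makes areas, perimeters, splits and Gaussian masses
  exact (interval arithmetic and `pnorm` products); property tests hold
  them to 1×10⁻⁹ relative against independent sweep/clip oracles.
* The primary-collimator cap (circle of 15 cm radius at the extra-focal
  plane, large enough never to clip jaw-defined DEVs up to 40 × 40 cm²)
  is clipped by inscribed chords on y sub-slabs of 0.1 cm.
* The optimizer is Levenberg–Marquardt with box bounds
  (`minpack.lm::nls.lm`), iteration cap 400, `ftol` 1×10⁻⁶, and a
  function-evaluation budget wide enough that the iteration cap is the
  binding control.  Noise-free tables (SD 0) fall back to nominal 0.1%
  weights.
* Test problem sizes: the full synthetic campaign is 341 fields; oracle
  equivalence runs 50 random DEVs and 200 random apertures; the noisy
  recovery check holds out every fourth MLC square from the four longer
  series and pools ~18 predictions.  The complete suite runs in about a
  minute on one CPU.

## Worked example

```{r example}
geom <- machine_geometry()
field <- field_spec(jaw_square(20), mlc_bank_square(10))
sc_mlc_field(field, geom, reference_apratio_model())
sc_total(field, reference_dsm_params(), reference_apratio_model(), geom)
```

## Known limitations

The region-activation convention for pure category-2/3 fields (the
as-written evaluation at $FP = 0$) makes $S_{c,MLC}$ deviate from unity
by several percent at the extremes of the square series under the
reference calibration; with re-fitted parameters this is absorbed, but
users comparing against the shipped values should be aware the convention
is part of the calibration.  Off-axis points, wedges,
flattening-filter-free beams, leaf transmission, interdigitation
constraints and DICOM-RT ingestion are out of scope; apertures come from
plain-text field files or the template functions.
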
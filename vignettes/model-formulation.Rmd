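---
title: "Model formulation and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model formulation and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcaim)
```

## What the model computes

`rcaim` is a reduced-complexity air quality model for *interventions*: it
estimates the steady-state, annual-average change in fine particulate
matter (PM2.5) concentrations caused by a marginal change in emissions of
five precursors — primary PM2.5, VOC, NOx, NH3 and SOx.  It does not
predict absolute ambient concentrations; its state variables are
concentration *changes*, which may be negative for emission reductions.

The underlying picture is the reaction-advection-diffusion balance for
each of nine tracked species (primary PM2.5; the gas/particle pairs
VOC/SOA, NOx/pNO3, NH3/pNH4; and SOx with its irreversible product pSO4):

$$\frac{\partial C_i}{\partial t} =
  -\nabla\cdot(\vec v\, C_i) + \sum_j R_{ij} + E_i - d_i$$

with molecular diffusion neglected as negligible next to advective and
turbulent transport.  The model discretizes this system on a
variable-resolution grid using *annual-average* fields, iterates forward
in pseudo-time with a CFL-limited step, and stops when the
population-weighted mean total-PM2.5 change no longer moves.  Because
every operator is linear in the concentrations, the steady solution is
linear in the emissions: doubling a scenario doubles the response, and
scenarios superpose.  The test suite verifies this directly, and also
verifies that the iterated steady state agrees with a direct solve of the
assembled linear system on small grids.

## Three-way wind decomposition

Annual averaging would destroy most transport information if the wind
entered only through its annual mean.  The wind and concentration are
therefore split into three parts: the annual mean, the deviations
resolved by the hourly driving data, and sub-hourly turbulence.  This
yields three transport operators:

1. **Mean advection** — first-order upwind fluxes of the annual-mean wind
   across each cell face.  The scheme is applied in flux form: each face
   flux debits the upwind cell and credits the downwind cell, so interior
   advection conserves mass exactly even where cell sizes differ.  Upwind
   differencing is numerically diffusive; the variable-resolution grid
   mitigates this where it matters by using small cells in populated
   areas.
2. **Deviation advection** — a symmetric, diffusion-like exchange
   proportional to the annual-mean *absolute deviation* of the wind
   (`mean(|u - mean(u)|)`).  A wind that blows +2 m/s half the year and
   −2 m/s the other half has zero mean wind but exchanges mass at 2 m/s
   symmetrically.  Deviation exchange is applied on horizontal faces
   only: the field archive carries no vertical deviation, vertical
   sub-annual variability being the business of the mixing closure, and
   the CFL constraint correspondingly uses only the mean vertical wind.
3. **Mixing** — sub-hourly turbulence, parameterized below.

The two Reynolds cross terms (mean-by-unresolved and
deviation-by-unresolved) are dropped; they represent a small fraction of
transport, and no annual-average parameterization for them is
established.

## Local–nonlocal mixing

Within the boundary layer the model combines local eddy diffusion
(coefficients `Kzz`, and `Kxx`/`Kyy` horizontally) with a nonlocal
convective exchange: the ground cell vents mass upward at rate `M2u`
(s⁻¹), distributed over the boundary-layer cells of its column, and each
elevated cell returns mass directly to the ground cell at its own rate
`M2d_i`.  Above the boundary layer and horizontally, only the eddy terms
act.

The printed form of such schemes leaves one choice open: whether the
downward branch cascades layer-by-layer or returns directly to the
ground.  We implement the direct-return reading with upward distribution
weights proportional to `M2d_i * dz_i`.  Under this reading the scheme
conserves column mass for *any* coefficients, and a uniform column is an
exact fixed point precisely when

$$M2u \cdot \Delta z_{ground} = \sum_i M2d_i\, \Delta z_i$$

holds over the boundary-layer cells.  The field generator enforces this
relation hour by hour (and hence after averaging), and both properties —
conservation and the uniform fixed point — are pinned by a dense matrix
oracle in the tests.

Boundary conditions: concentration changes are zero outside the lateral
and top domain edges (advective outflow is a pure loss, inflow carries
zero; deviation and diffusive exchange see a zero ghost value), and the
ground is impermeable to transport — removal at the surface happens only
through dry deposition.

## Chemistry and partitioning

**Sulfur.** SO2 oxidizes irreversibly to particulate sulfate with
first-order kinetics, `dC = kS * C_SOx * dt`.  The annual-average rate
constant is the mean of hourly rate constants — a gas-phase termolecular
SO2 + OH term evaluated at the hourly temperature and OH concentration
plus an effective aqueous term proportional to cloud fraction and liquid
water — *not* the rate constant evaluated at annual-mean inputs; the
distinction matters because the dependence is nonlinear, and a test
asserts the inequality on a convex case.

**Reversible pairs.** NOx/pNO3, NH3/pNH4 and VOC/SOA partition
instantaneously: at the end of every step the pair total `T = C_g + C_p`
is redistributed as `C_p = fp * T`, `C_g = T - C_p` (the subtraction form
keeps the pair total exact to the last bit).  The annual-average marginal
partitioning fraction `fp` is estimated from hourly gas/particle mass
series as the mean over consecutive steps of
`Δm_p / (Δm_p + Δm_g)`.  Two degenerate cases are not defined by that
ratio and are resolved as follows: steps with zero total change are
skipped (reducing the effective n), and per-step ratios outside [0, 1]
(opposite-signed phase changes) are clamped to the unit interval.  This
keeps `fp` a valid fraction; the estimator is invariant to uniform
rescaling of the masses.

Partitioning is applied *after* all other operators in a step.  All other
operators read start-of-step concentrations, so their order is
immaterial; partitioning is the one order-sensitive operation, hence its
fixed position.

Gas species are tracked as the mass of the particle-forming moiety (SOx
as SO4-equivalent, NOx as NO3-equivalent, NH3 as NH4-equivalent, VOC as
SOA-potential mass).  The molar conversion happens once, at emission
ingestion; chemistry and partitioning then conserve tracked mass without
stoichiometric bookkeeping inside the solver.

## Deposition

Dry deposition acts in ground-layer cells only, as a deposition velocity
from serial resistances, `v_dd = 1/(r_a + r_b + r_c)` for gases; for
particles the settling-velocity modification
`v_dd = v_s + 1/(r_a + r_b + r_c + r_a r_b v_s)` is used with the fixed
model aerosol (diameter 0.3 µm, density 1830 kg m⁻³; `v_s` ≈ 8 µm/s
from Stokes settling with the Cunningham correction).  Wet deposition is
a first-order loss `dC = -C * r_wd * dt` in every cell, with separate
annual-average scavenging rates for particles, SO2 and other gases
(cloud-fraction-weighted in-cloud plus precipitation-driven below-cloud
terms).

## Time stepping and convergence

The pseudo-time step obeys the CFL bound

$$\Delta t = \frac{C_{max}}{3\,\max_i \max\!\left(
  \frac{|U_i|+|\tilde U_i|}{\Delta x_i},
  \frac{|V_i|+|\tilde V_i|}{\Delta y_i},
  \frac{|W_i|}{\Delta z_i}\right)}$$

with `Cmax = 1` by default and a calm-wind floor of 10⁻³ m/s in the
denominator so a windless archive still yields a finite step.  Because
the coarse high-altitude cells pair large sizes with fast winds, the step
is typically limited by the small ground-level cells.

Convergence (the driving literature does not fix a criterion) is declared
when the population-weighted mean total-PM2.5 change moves by less than a
relative tolerance (default 10⁻⁶) over a 100-iteration monitoring
window, with an absolute floor (default 10⁻⁹ µg/m³) so that all-zero
scenarios converge immediately.  The steady solution itself is a fixed
point of the step map and therefore independent of `dt`; halving `dt`
changes the toy-suite solutions by well under 0.5%, and the iterated
solution matches a direct linear solve to 10⁻⁶ relative on small grids —
both are tested.

## The variable-resolution grid

The horizontal domain is tiled by square columns that refine
quadtree-style where population is dense: a column splits while its
footprint population exceeds a threshold and its edge exceeds the minimum
size.  Edge lengths follow a divisor ladder from the base size; the
default `48 km / (2, 2, 2, 2, 3)` reproduces a 48–1 km range exactly
(48, 24, 12, 6, 3, 1 km).  Horizontal refinement applies only below a cap
height (default 1500 m): concentration fields smooth out with altitude,
so all layers above the cap use the base tiling.  Faces between unequal
neighbours carry fractions `f` (the share of a cell's face touching each
neighbour); interior fractions close to 1, tilings are exact partitions
of the domain, and construction is deterministic — all enforced by
`validate_grid()` and the test suite.

A second, dynamic strategy re-examines the grid during the run: a
column's refinement score is its ground-cell population density times the
largest absolute total-PM2.5 difference to any horizontal neighbour;
columns above a split threshold refine, and complete sibling sets below a
quarter of that threshold merge.  Concentrations transfer conservatively
(children inherit the parent value; merges volume-average), so refinement
preserves total mass to rounding.  Both thresholds are configuration
values rather than constants, since no reference values are available for
them.

## Emissions, plume rise, units

Scenarios are GeoJSON features (points, lines, polygons) with annual
amounts for `VOC`, `NOx`, `NH3`, `SOx`, `PM2_5` — short tons/yr by
default, matching the convention of this model family, with kg and tonne
options — and optional stack attributes `height`, `diam`, `temp`,
`velocity`.  Amounts are allocated to cells by area weighting (count,
length or area for points, lines, polygons), converted with a Julian year
of 3.15576×10⁷ s.  Negative amounts (reductions) are handled identically
to additions throughout, including plume rise.

Elevated sources inject at the layer containing stack height plus Briggs
final plume rise, computed from stack buoyancy and momentum fluxes using
the *pre-averaged* inverse windspeed powers stored in the archive
(`mean(1/u)` for the neutral/unstable branches, `mean(u^{-1/3})` for the
stable branches), taking the larger of the buoyant and momentum rises.
The archive also carries `mean(u^{-1.4})` for compatibility with extended
branch sets, though the implemented formulas do not consume it.  For line
and polygon sources the column at the geometry centroid supplies the
plume parameters.

## The synthetic field archive

Real applications of this model class derive their per-cell fields from a
comprehensive chemical transport model.  No such output ships here;
instead `synthesize_archive()` generates a physically plausible archive
by synthesising hourly series per column — diurnal and seasonal cycles in
temperature, boundary-layer height, heat flux, OH, cloud and
precipitation, with noise — and running exactly the hourly-to-annual
estimators a preprocessor would run (`average_rate_constant()`,
`partitioning_fraction()`, `average_mixing_coefficients()`,
`average_deviation()`, `wet_scavenging_rates()`).  Defaults emulate
mid-latitude continental conditions: prevailing flow with ground speeds
of 1–8 m/s rising toward 30 m/s at the domain top, hourly variability of
about half the mean speed, boundary layers of 300–1500 m, and 8760-hour
series behind every average.

What the generator does *not* emulate: terrain and land-use contrasts,
correlated synoptic weather, seasonal covariance between precipitation
and boundary-layer depth, or realistic emission-landscape chemistry.
Passing tests therefore demonstrate that the numerics implement the
stated equations and conservation properties — not that predictions match
a comprehensive model over real terrain, which requires real preprocessor
output and is out of scope here.

## Evaluation statistics

`compare()` implements the paired statistics used throughout this model
family: mean bias, mean error, mean fractional bias and error (per-pair
denominators `Y + X`), model ratio, least-squares slope and intercept,
and squared Pearson correlation, all optionally weighted (for
population-weighted evaluation).  Pairs with `Y + X = 0` are excluded
from the fractional metrics — and pairs with `X = 0` from the ratio —
with exclusion tallies reported, since those ratios are undefined.  MFB
and MFE are stored as fractions and rendered as percentages.  For
weighted comparisons both the weighted and unweighted R² are computed;
the weighted one is reported by default.

## Problem sizes and defaults used in the shipped scenarios

The demonstration scenario (`make_demo()`) uses a 96×96 km domain with a
12 km base grid refining to 3 km over a single population cluster, six
vertical layers to 3 km, an 8760-hour synthetic year, and a single
ground-level point source emitting 100 short tons/yr of primary PM2.5 at
the cluster centre — a deliberately small domain that a laptop solves in
seconds while still exercising refinement, transport, deposition and the
exposure summaries.  Unit and property tests run on still smaller toy
grids (1–100 cells) where dense matrix oracles and closed forms are
exact.  The archive generator's physical defaults are not scaled down;
only domain extent and series length are test-sized where speed matters.

## Known limitations

- Deviation advection is horizontal-only (no vertical deviation field).
- Ozone, aerosol thermodynamic coupling between inorganic species, and
  time-resolved output are out of scope; concentration changes of the
  nitrogen species ignore nonlinear interactions with sulfate, which the
  model family is known to represent poorly in SO2-rich scenarios.
- Shapefile input is not supported (GeoJSON only), and the field archive
  uses a plain-text table layout rather than NetCDF.
- `r_c` for particles enters the deposition velocity as an additional
  serial resistance; the archive's `rc_particle` is generated from a
  friction-velocity collection-efficiency form rather than a full
  size-resolved scheme (the model aerosol has a single fixed size).
- Plume rise uses final-rise Briggs formulas only; stack-tip downwash and
  partial penetration of elevated inversions are not represented.
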
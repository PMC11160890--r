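---
title: "The myolattice half-sarcomere model: mechanics, kinetics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The myolattice half-sarcomere model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(myolattice)
```

## What the model is

`myolattice` simulates one half sarcomere — the contractile unit from the
M-line (thick filament midpoint) to the Z-disk — as a three-dimensional
spring lattice. Four myosin-containing thick filaments and eight
actin-containing thin filaments are chains of linear springs whose nodes are,
respectively, myosin crowns (triplets of heads every 14.3 nm, heads 120
degrees apart azimuthally, adjacent crowns rotated 60 degrees) and actin
binding sites (every 38.7 nm). Transverse periodic boundary conditions make
each thick filament interact with six thin filaments, so the unit tiles the
hexagonal myofilament lattice. Titin connects each thick filament tip to the
Z-disk as an exponential spring. The 14.3/42.9 nm myosin repeat is out of
register with the 38.7 nm actin repeat, so which heads can reach a site
depends on position along the filament and on filament strain — the reason
the model is spatially explicit rather than mass-action.

Each myosin head is two springs: a torsional spring at its base (stiffness
`k_theta`, equilibrium angle `r_theta`) and a linear spring along the arm
(`k_r`, `r_r`). The head cycles through three states — unbound, weakly
bound, strongly bound — and the power stroke (weak to strong) is a change of
both equilibria (47.16 to 73.20 degrees; 19.96 to 16.47 nm). The radial
distance between filament surfaces (the actin-myosin *face spacing*, related
to the x-ray d10 spacing by a lattice geometry factor) is **prescribed**: it
modulates binding and force but has no dynamics of its own.

Each timestep performs the model loop:

1. **thermal forcing** — every unbound head redraws each spring displacement
   from its Boltzmann distribution (Gaussian, variance `kT/k`);
2. **stochastic transitions** — per-head rates are evaluated at the current
   geometry and at most one transition per head is drawn;
3. **force balance** — every filament node is moved until the net force on
   each node is below tolerance, with the M-line and the (strain-driven)
   Z-disk held fixed;
4. the net axial force is read off at the M-line-proximal thick nodes.

## Rate functions and their orientation

With `U0 = 0` (unbound reference), `U1 = alpha1 + E_pre/kT` and
`U2 = alpha2 + E_post/kT` (elastic energy of the bound head against the
pre-/post-stroke equilibria, in kT):

* binding `r12 = tau * exp(-d^2) + 0.005` per ms, `d` the distance from the
  thermally displaced head tip to the site (axial offset and radial
  mismatch);
* unbinding `r21 = r12 * exp(U1 - U0)`;
* power stroke `r23 = A * (1 + tanh(C + D (U1 - U2)))`;
* reverse stroke `r32 = r23 * exp(U2 - U1)`;
* detachment `r31 = max(0, G U2 + H)`, and `r13 = 0`.

The reverse-rate orientation is chosen so that Boltzmann equilibrium holds
(`p_bound/p_unbound = exp(-(U1 - U0))`) and, critically, so that the
unbinding rate **grows without bound** as a dragged head's elastic energy
rises: because `r12` has the constant 0.005/ms floor, `r21 >= 0.005 *
exp(U1)` forms an "infinite well" that releases overstrained heads almost
instantly. This is what keeps bound-head axial strains under ~10 nm during
rapid shortening and prevents the unphysical multi-tens-of-nanometre drags
that otherwise dominate dynamic simulations. For a bound head, the `r12`
entering `r21` is evaluated at the distance between the site and the head's
*rest* tip position (the spatial displacement the bound springs store).

Transition probabilities are `1 - exp(-r dt)`; competing transitions from one
state share a single uniform draw partitioned proportionally to their rates,
so the total per-step transition probability is exact for the embedded jump
chain and never exceeds 1 even where `r12 ~ 72/ms` saturates binding. One
head per site: simultaneous attempts on a site are resolved by a randomized
first-come order and later heads are refused.

## Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `k_thick`, `k_thin` | 2020, 1760 | pN/nm per segment | filament segment stiffness |
| `k_theta`, `k_r` | 4000, 16 | pN nm/rad, pN/nm | head torsional / arm stiffness |
| `r_theta`, `r_r` | 47.16/73.20 deg, 19.96/16.47 nm | | pre/post stroke equilibria |
| `tau, A, C, D, G, H` | 72, 0.8, 6, 0.2, 0.6, 0.02 | per ms (C, D unitless) | rate constants |
| `kT` | 4.11 | pN nm | thermal energy (~25 C) |
| `alpha1`, `alpha2` | -2, -122.7 | kT | binding / stroke free-energy baselines |
| titin `a`, `b` | 260, 4 | pN, 1/um | exponential titin `a e^{b dL}` |
| `frequency`, strain | 25, 0.10 | Hz, peak-to-peak | work-loop drive |
| face spacing | 15 | nm | reference actin-myosin surface gap |
| `muscle_density` | 1060 | kg/m^3 | mass-specific work scaling |

The lattice geometry factor is 2/3 (vertebrate) or 1/sqrt(3) (invertebrate
flight); with combined filament radii of 12.5 nm these reproduce the
standard conversion pairings (d10 47.5 nm to 15.0 nm face spacing in flight
muscle; 38 nm to 12.8 nm in vertebrate muscle) within 0.1 nm.

### The free-energy baselines are calibration constants

`alpha1` and `alpha2` (the chemical free-energy drops of binding and of the
power stroke, on top of elastic energy) are not measurable directly and are
calibrated, not taken from data. `alpha1 = -2` kT makes attachment at a
perfectly aligned site favourable by e^2. For `alpha2` the natural anchor —
a strongly bound crossbridge bearing ~8-10 pN on average in an isometric
tetanus — turns out to be unattainable under the default stiffnesses: the
force borne by a strong head at the binding locus is ~90 pN, fixed by
`k_theta`, `k_r` and the stroke's equilibrium shift, for *every* choice of
`alpha2` that lets strokes fire at all (the scan lives in
`scripts/calibrate_offsets.R`). We therefore set `alpha2` so the power
stroke is thermodynamically neutral exactly where heads bind at the 15-nm
reference spacing (`alpha2 = -E_post(locus)/kT = -122.7` kT): the stroke is
then the primary force-producing step, isometric tetani are stable with
50-60 pN per bound head and tetanic stress around 60-70 mN/mm^2, and the
model's `r31` detachment activates over the physiological strain range.

## Numerical choices

* **Solver.** Force balance is a Newton iteration over all free nodes: the
  constant filament-spring stiffness matrix is assembled once per geometry;
  crossbridge second derivatives and the titin tangent stiffness are added
  each iteration and the dense system solved by LU. Residual tolerance
  1e-3 pN per node (asserted every timestep in the tests), iteration cap
  100, Newton steps capped at 5 nm to keep the crossbridge linearization
  honest. The crossbridge-free run of each thin filament between the
  overlap region and the Z-disk is condensed into one equivalent series
  spring — exact for a static linear chain.
* **Kinetic subcycling.** At 25 Hz and 10% strain the filaments slide up to
  ~10 nm per millisecond — several binding-well widths. Transition hazards
  evaluated once per 1-ms step would hold dragged heads far beyond where
  `r21`/`r31` should have released them, and net work then depends strongly
  on `dt`. Each mechanical step therefore runs `kinetic_substeps` (default
  8) diffusion/transition subcycles with the thin filaments translated with
  the Z-disk in substep increments; balance and recording stay on the
  mechanical step. Work-loop work is then self-convergent across
  `dt = 1, 0.5, 0.25` ms (a tested property).
* **Timestep and cycles.** `dt = 1` ms (rates are per ms); work loops run 1
  warmup cycle plus 16 recorded cycles (20 for the lattice-trajectory
  comparisons), matching the averaging used for the reported means and
  standard deviations. The unit tests run a reduced lattice (6 crowns,
  420-nm half sarcomere) for speed; acceptance computations use the full
  default geometry (20 crowns, 240 heads, 1.25-um half sarcomere,
  sarcomere length 2.5 um).
* **Determinism.** Each trial takes one integer seed (`set.seed` at entry);
  the package is single-threaded, so runs are bit-reproducible. Sweeps
  reseed each condition as `seed + i - 1`.
* **Degenerate inputs.** Non-positive spacings, stiffnesses or rates are
  rejected at construction with the offending field named; a face spacing
  whose conversion would be non-positive, an unbalanced state queried for
  force, and an open strain loop handed to the work integral are all
  errors, not warnings.
* **Stress and mass scaling.** Published work-loop results are in mN/mm^2
  and J/kg but the normalization constants are rarely printed. We use a
  thick-filament areal density of `2/(sqrt(3) (sqrt(3) d10 1e-9)^2)` at the
  reference d10 (time-invariant, so density modulation cannot generate
  spurious loop area) and muscle density 1060 kg/m^3; both are
  config-exposed, and all reported work values scale linearly with the
  density constant.

## Lattice-spacing trajectories and the synthetic in vivo trace

Three modes couple the radial spacing to the strain cycle: `isolattice`
(constant), `poisson` (`d10(t) = d10_0 (1 + dL/L)^(-nu)`; `nu = 0.5` keeps
`d10^2 L` exactly constant — isovolumetric; `nu = 0` constant), and
`prescribed` (any periodic d10-change table). `make_invivo_trace()` builds a
**synthetic** stand-in for measured in vivo lattice dynamics: the
fundamental Fourier component of the isovolumetric trajectory, scaled to
0.75 amplitude and phase-advanced by 0.1 cycle, reproducing the qualitative
"smaller and earlier" character of insect flight-muscle lattice spacing
changes. It is a fixture: it contains no harmonics beyond the fundamental,
no stochastic measurement noise, and no activation-dependent radial forces,
so conclusions drawn from it speak to trajectory *timing and amplitude*
only, not to any measured trace.

## What passing tests do and do not show

The test suite verifies the analytic rate identities and detailed balance to
machine precision, Boltzmann sampling statistics at 1e5 draws, solver
residuals at every step, a rigid-filament force oracle against brute-force
summation, exact zero net work for passive elastic cycles, the exact
isovolume invariant, and timestep self-convergence. These establish that the
simulator faithfully integrates the model as specified.

Two acceptance-level checks about the *work landscape* are currently not
met, and are left failing deliberately rather than tuned away. Under the
default stiffened head springs, the elastic energy stored by the stroke at
the binding locus never exceeds the elastic energy at which the
strong-state escape rates activate, so every bound episode under fast
sliding returns at least as much energy to the lattice as it delivers: net
cycle work is slightly negative (about -0.1 J/kg) at *all* phases of
activation and lattice spacings, instead of ranging from roughly -3.5 to +1
J/kg with a 1-nm sign switch. The model as parameterized is an excellent
isometric force generator and a weak dynamic motor. Reproducing the
published dynamic work structure evidently requires energetic details (or
unit conventions) beyond the printed constants; the calibration scan and a
single-head constant-velocity passage analysis that document this are kept
with the package sources. All headline quantities are nevertheless computed
honestly by `scripts/acceptance.R` and reported as measured.

## Known limitations

* Lattice spacing is prescribed; crossbridge radial forces are computed but
  do not deform the lattice (no radial force balance).
* Titin is a passive exponential spring with a 260-pN preload at rest; no
  calcium-dependent stiffening. At the 2.5-um operating length its
  stiffness exponent (4-10 /um) does not measurably move net work — the
  titin sweep is a flatness check, not a null result about longer
  sarcomeres.
* One binding site per 38.7-nm target zone, one head per site; no
  inter-head cooperativity beyond mechanical coupling through filament
  compliance.
* Fluid interactions, sarcomere-boundary effects and multi-sarcomere
  chains are outside scope.
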
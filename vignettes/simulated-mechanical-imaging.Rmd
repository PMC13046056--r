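---
title: "Simulated mechanical imaging on compressible breast phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated mechanical imaging on compressible breast phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Mechanical imaging (MI) records the stress distribution on the breast surface
during mammographic compression with a grid pressure sensor of 1 cm$^2$
spatial resolution mounted on the stationary paddle. Because the surface
stress pattern reflects the local stiffness of the underlying tissue, MI is
sensitive to breast density — the volume share of stiff fibroglandular
("dense") tissue relative to soft adipose tissue. `mivct` implements an
in-silico emulation of that measurement: a virtual clinical trial in which
the patient is a procedurally generated, mechanically compressible software
breast phantom. This vignette explains each stage of the model, the
parameters that matter, the numerical choices, and what the package's tests
do and do not establish about real data.

## Phantom anatomy from gradient noise

Tissue texture is generated by seeded 3D Perlin gradient noise. Unit
gradient vectors sit at the intersection points of a cubic lattice of cell
size $c$; the noise at a point is the fade-interpolated sum of dot products
between each enclosing corner's gradient and the distance vector to the
point. Two properties matter downstream and are asserted by tests: the noise
is exactly zero at lattice points, and it is a pure function of the seed, so
any sub-region is reproducible independently of evaluation order (gradients
come from a counter-based hash of the seed and lattice coordinates, not from
a sequential RNG stream). Gradient directions are drawn by rejection
sampling the unit cube to the unit ball and normalising, which is exactly
uniform on the sphere.

Octaves superimpose copies of the noise with the lattice spacing halved and
the amplitude multiplied by the persistence $p$ at each level; the sum is
divided by $\sum_i p^i$ so the output range does not depend on the octave
count. Defaults — 4 octaves, $p = 0.5$, base cell 2.5 cm — were chosen once
to give centimetre-scale lobular structure inside a 17 cm breast with
visible fine texture; they are configuration parameters, not fitted values.

## Breast shape, tissue table and density calibration

The breast solid is the union of two quarter ellipsoids joined at the
craniocaudal ($x = 0$) plane and clipped to $z \ge 0$ (the chest wall),
spanning 17 cm × 7.5 cm × 3.7 cm (about cup size A). $y$ is the compression
(mediolateral) axis. Both quarters default to semi-axes (8.5, 3.75, 3.7) cm;
unequal anterior/posterior $x$ semi-axes are supported.

Voxels carry discrete adipose fractions from a preset table, 1.00 (pure
adipose) down to 0.40 (40% adipose / 60% fibroglandular) — by default 13
levels in steps of 0.05. Thresholding turns noise into anatomy: field values
below the threshold become pure adipose, values above are rescaled linearly
from [threshold, field max] onto [1.00, 0.40] and snapped to the nearest
table level, preserving graded glandular structure. The dense percentage of
a phantom is defined as the volume-weighted mean fibroglandular fraction,
$100 \cdot \mathrm{mean}(1 - v)$, over in-breast voxels — a mixture-weighted
definition rather than a voxel count, because voxel values are themselves
mixtures.

Lowering the threshold monotonically increases the dense fraction, so
bisection calibrates a threshold to any target below the table's 60%
ceiling; convergence is declared within 0.25 percentage points. An "aging
series" thresholds one identical noise field at several calibrated values
(targets 9, 27, 43, 53, 56% by default), so all densities share the same
underlying anatomy — only the adipose/fibroglandular balance changes, as in
age-related involution. Tests assert nesting: a voxel can only become denser
as the target rises.

## Mesh and material assignment

The solid is meshed by clipping a structured hex grid to the shape (a hex is
kept when its centre is inside) and splitting each hex into 6 tetrahedra
along a common main diagonal (Freudenthal/Kuhn), which is conforming across
neighbouring cells and conserves volume exactly. This is deterministic and
dependency-free; it does not reproduce any particular unstructured mesh, and
the full-scale profile merely matches the order of magnitude (~10^5
elements) of the reference experiment.

Each element's modulus is the linear mixture
$E = \bar v E_\text{adipose} + (1 - \bar v) E_\text{gland}$ with
$E_\text{adipose} = 20$ kPa and $E_\text{gland} = 80$ kPa, where $\bar v$ is
the element-mean adipose fraction estimated by equal-weight quadrature with
nearest-voxel lookup (no interpolation, honouring the discrete table).
Because the integrand is piecewise constant on voxels, low-order polynomial
rules are the wrong tool: the classic 4-point rule leaves element moduli up
to ~2.5 kPa away from a converged value at default resolutions, while the
35-point interior barycentric lattice (the default) is within 1 kPa of an
816-point rule. This is why the default quadrature is a dense equal-weight
lattice rather than a Gauss-type rule; both remain available through
`quadrature_order`. Averaging voxel values and then mapping is equivalent to
averaging moduli because the mixture map is affine.

## Compression mechanics

Compression is a quasi-static, large-deformation finite-element solve with
the compressible neo-Hookean energy
$$ W(F) = \tfrac{\mu}{2}(I_1 - 3) - \mu \ln J + \tfrac{\lambda}{2}(\ln J)^2, $$
stress-free at the reference configuration, with per-element Lamé parameters
from $(E, \nu)$. The Poisson ratio is not dictated by the tissue moduli
alone; soft tissue is nearly incompressible and the package defaults to
$\nu = 0.49$. Linear 4-node tetrahedra with one-point quadrature are used;
at $\nu = 0.49$ this element is locking-prone, which inflates stiffness
somewhat on coarse meshes — a documented limitation ($\nu$ is configurable
downward, and the homogeneous verification problem, where linear elements
represent the uniaxial state exactly, matches the closed form to < 3%).

The paddles are modelled as rigid planes normal to $y$ rather than as
meshed high-modulus plates: the reference setup assigned plates a high
modulus precisely to emulate rigidity, and analytic planes realise that
intent while removing tens of thousands of degrees of freedom. Contact is a
frictionless node-to-plane penalty: a surface node penetrating by $g$
receives a normal force $k \, g \, a$, with $a$ its tributary area (one
third of adjacent boundary-face areas projected onto the plate plane) and
$k$ the penalty stiffness (default 2000 N/cm$^3$, giving penetrations well
under 10% of an element edge; doubling $k$ changes the total reaction by
< 1%). Boundary conditions mirror the clinical setup: the chest-wall
surface ($z = 0$) is fixed in $z$, surface nodes within 8 mm of either
plate plane are fixed in $x$, and one deterministic anchor node touching
the stationary plate is fixed in all directions. The moving plate travels
3.76 cm along $-y$ — about half the phantom's 7.5 cm width — measured from
the initial configuration, where the plates start at the phantom's widest
$y$ extent.

Each of the (default 20) ramp increments is solved by damped Newton
iteration with an analytically consistent tangent (verified against finite
differences to 1e-6 relative), sparse supernodal Cholesky factorisation
with an LU fallback for indefinite intermediate tangents, step-halving line
search that also rejects element inversion ($J \le 0$), and recursive step
bisection if an increment fails outright. Convergence is declared when the
free-DOF residual drops below `tol` (default 1e-6) times the contact-force
scale. The reported reaction force is the total $y$-force on the moving
plate; the anchor node's constraint reaction is attributed to the
stationary plate it touches, which makes the moving/fixed force balance an
exact equilibrium statement (tests require agreement within 1%, observed at
rounding level).

## The MI map and its summaries

The simulated sensor output bins each contacting node's $y$-force into the
1 cm × 1 cm patch of the stationary plate containing its deformed $(x, z)$
position, then divides by the patch area (1 N/cm$^2$ = 10 kPa). Scalar
summaries follow the sensor conventions: total force (N), contact area =
number of patches above a 0.1 kPa floor (cm$^2$), and mean stress = total
force / contact area. Reported tables round force and stress to integers,
mirroring the conventional presentation; machine-readable outputs keep full
precision. A retention adjustment multiplies the mean stress by 0.27, the
in-vivo fraction of applied force transmitted through the central breast
area (the chest wall absorbs the rest), for order-of-magnitude comparison
with the reported in-vivo average of 2.5 kPa.

The patch-count contact area deserves a caveat. At the scaled-down ("desk")
resolution the contact rim is resolved by ~0.5 cm node spacing, and two to
three fringe patches carrying under 2 kPa (less than 1% of the map maximum)
drift in and out of the 0.1 kPa floor across the aging series: measured
areas were 56/57/55/54/54 patches for the five densities, rather than
exactly equal as observed at full scale. Counting patches above 2 kPa
yields an identical 48 patches for all five densities, confirming that the
load-bearing footprint is density-independent and that the variation is a
rim-resolution artifact of the coarse profile, not a property of the model.
The package keeps the configured 0.1 kPa floor and reports this sensitivity
rather than adjusting the definition post hoc.

## Problem sizes, profiles and determinism

Two bundled profiles fix the study conditions: `paper` (1 mm voxels,
0.23 cm mesh edge, ~1.2 × 10^5 tets, 40 load steps) reproduces the
full-scale geometry, and `desk` (3 mm voxels, 0.5 cm edge, ~1.2 × 10^4
tets, 20 steps) is the scaled-down configuration used by the test-suite and
acceptance runs; a five-density desk series completes in a few minutes on
one CPU. Everything downstream of the seed is deterministic: rerunning a
configuration reproduces byte-identical machine-readable summaries, and
every output JSON embeds the configuration hash and seed.

On the desk profile with the default seed, the five-density series gives
reaction forces rising strictly from ~75 N (9% dense) to ~158 N (56%
dense) with mean stresses of ~13 to ~29 kPa — the same direction and
magnitude as the full-scale reference values (65–133 N, 13–27 kPa), with
the expected upward stiffness bias of a coarse, locking-prone mesh. These
numbers are recomputed, not stored: the acceptance script and the test
suite derive them from scratch at run time.

## What the synthetic data do and do not show

The generator emulates the statistical texture of adipose/fibroglandular
anatomy, its density spectrum, and the bulk mechanics of plate compression.
It does not include skin, Cooper's ligaments, pectoral muscle, the chest
wall's force absorption, lesions, gravity or prestress, friction, or sensor
noise and calibration error. Passing tests therefore establish internal
consistency (oracle agreement, conservation, convergence, monotone
density–force response and magnitude agreement with the full-scale
reference experiment); they do not establish that absolute simulated
stresses match in-vivo MI, which the retention adjustment only reconciles
to order of magnitude. The stiffness moduli themselves span wide
physiological ranges (9–31 kPa adipose, 14–83 kPa glandular in the
elastography literature); both end-members are configurable.
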
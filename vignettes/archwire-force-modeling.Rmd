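---
title: "Modeling archwire forces: calibration, the sextic stiffness law, and tissue response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling archwire forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archforce)
library(ggplot2)
```

## The problem

A nitinol archwire ligated into orthodontic brackets is an elastic spring
bent away from its manufactured shape. As it relaxes it pushes each tooth
with a force that depends on *where* along the wire the tooth sits and
*how far* the wire is deflected there. archforce models this force system
in three steps:

1. **Calibration.** A clamped-clamped wire is loaded with a point force
   $F$ at a station and the deflection $x$ at the load point is probed.
   The pointwise elastic constant is $k = F/x$ (N/mm). Because the model
   is linear, $k$ is independent of $F$ — the calibration sweep verifies
   this to $10^{-9}$ relative and collapses each station to one number.
2. **The sextic stiffness law.** Stations are expressed in the curvilinear
   (arc-length) coordinate $y$, and the seven nodes
   $(0, 0), (y_1, k_1), \dots, (y_6, k_6)$ determine a degree-6
   interpolating polynomial
   $$k(y) = a y^6 + b y^5 + c y^4 + d y^3 + e y^2 + f y + g,$$
   with $g = 0$ pinned by the zero node. The elastic force on a bracket at
   coordinate $y$ with measured wire deformation $x$ is then
   $F = k(y)\,x^n$, with $n = 1$ for metallic wires ($n \le 3$ supported
   for non-metallic ones).
3. **Tissue response.** The per-bracket forces load a linear-elastic
   tetrahedral model of teeth in bone, producing displacement, strain,
   von Mises stress and strain-energy maps with their maxima.

## The virtual load-deflection laboratory

The wire is a slender circular beam (0.3556 mm diameter against roughly
100 mm of length), so the solver is a 3D space-frame model: 2-node
elements carrying axial stiffness $EA$, torsion $GJ$ and Euler–Bernoulli
bending $EI$ in two planes, six degrees of freedom per node, both end
nodes fully clamped. For straight prismatic members with a node at the
load, Hermite beam elements are nodally exact, which gives the suite hard
oracles: the center-load deflection $FL^3/(192 EI)$ and the off-center
form $F a^3 b^3 / (3 E I L^3)$ are reproduced to $10^{-9}$ relative
regardless of element count.

```{r beam}
mat <- material("steel", 7800, 2.1e11, 0.3)
m <- discretize(straight <- wire_path(cbind(seq(0, 10, length.out = 201), 0, 0)),
                max_element_length = 1, stations = 5,
                section_diameter = 1, mat = mat)
sol <- assemble_and_solve(m, load_case(5, 0.3, direction = c(0, 0, 1), frame = "arc"))
c(solver = sol$deflection_mm,
  closed_form = 0.3 * 10^3 / (192 * (mat$E / 1e6) * m$I))
```

Two deliberate simplifications, both documented rather than hidden:

* **Small-displacement linear theory** is used even though the reference
  calibration data contain deflections of hundreds of millimeters at 10 N.
  The reference data's own $k$ columns are constant across that whole
  force range, i.e. they were produced by a linear solver too, and a
  linear model is exactly what the constant-$k$ protocol assumes.
* **The wire material preset** stores a Young's modulus of
  $8.3\times10^{7}$ Pa — three orders of magnitude below literature
  nitinol moduli. It is kept as given because it is internally consistent
  with the stored shear modulus and with the very large reference
  deflections. The `material()` object records the relative departure of
  each preset's $G$ from $E/(2(1+\nu))$ (the bone preset is off by about
  0.6%; the solver uses the stored $G$).

Stations are specified as chord coordinates $z$ (straight-line distance
from the wire end) and mapped to arc length with `chord_to_arc()`;
`discretize()` accommodates each station by snapping the nearest interior
grid node to it. Inserting extra nodes instead would create sliver
elements whose $1/L^3$ bending stiffness destroys the conditioning of the
system — this is a numerical choice, not a modeling one, and it keeps
every element within the requested size because the base grid is refined
by 3/2 when stations are present.

## Conditioning of the sextic fit

The monomial Vandermonde matrix over nodes up to $y = 59$ mm has a 2-norm
condition number near $5\times10^{10}$. A naive spreadsheet solve is
unreliable here; `fit_sextic()` uses a pivoted LU factorization with one
step of iterative refinement, warns above condition $10^{12}$, and
asserts the interpolation residual at every node ($\le 10^{-9}$
absolute). The tests cross-check the solved coefficients against an
independent Lagrange-basis expansion oracle, and round-trip known
degree-6 polynomials to $10^{-6}$ relative. Double precision recovers the
reference coefficients to about eight significant digits — comfortably
beyond the five digits the package asserts.

```{r fit}
law <- fit_sextic(reference_stiffness_nodes(), arch = "upper")
tidy(law)
glance(law)
```

Beyond the outermost node the sextic blows up, so `evaluate_k()` flags
extrapolation (several reference teeth sit at $y$ up to 73.11 mm, beyond
the last calibration node at 59 mm); between nodes the interpolant can
oscillate negative, so `evaluate_force()` returns the signed value and
`compute_tooth_forces()` reports magnitudes, which is how the reference
force tables are printed.

```{r lawplot, fig.width = 6, fig.height = 3.5}
autoplot(law)
```

## What the audit of the reference tables finds

`audit_reference_tables()` recomputes every published number of the
reference calibration case and reports, rather than repairs, two internal
conflicts in that dataset:

* the node table lists two $k$ values at $y = 20.04$ that differ by a
  factor of 10 (0.047418085 vs 0.004741799); the fit follows the column
  that is consistent with the published coefficients;
* of the two published coefficient sets ("upper" and "lower" wire), the
  "upper" set reproduces the per-tooth force tables of **both** arches to
  well under 1% per row (once magnitudes are taken), while the "lower"
  set reproduces neither — an apparent label swap. The package keeps both
  sets with their provenance and uses the reproducing set for
  force-table work.

```{r audit}
audit <- audit_reference_tables()
audit
```

## The synthetic data generators

No patient geometry ships with the package, so two generators stand in
for it; they emulate the *structure* of the clinical inputs, not any
specific patient:

* `generate_arch_curve()` builds a symmetric U-shaped arch
  ($y = d\,(1 - |t|^{p})$ across a width $w$, optionally tilted out of
  the occlusal plane and with seeded low-frequency waviness), uniformly
  resampled and scaled to an exact total length. Defaults target the
  reference wire lengths (152.12 mm upper before trimming to 109.68 mm).
  Resampling iterates to a fixed point so that the stored polyline is
  uniform in its own metric and resampling is exactly idempotent;
  trimming keeps the surviving vertices verbatim, since re-resampling
  would cut corners and change the trimmed length.
* `build_deformed_path()` displaces the wire at bracket sites by given
  offsets (defaults drawn from 1–9 mm, the range of the reference
  deformation tables), blending with compactly supported cosine bumps
  whose half-width stays below the site spacing, so each injected offset
  is attained exactly at its site and recovered by
  `measure_deformation()` within resampling error.
* `build_synthetic_tooth_model()` meshes a bone block with a structured
  Kuhn (6-tets-per-hex) subdivision, labels frustum-shaped teeth and
  facial bracket pads, and jitters interior nodes (seeded) so the mesh is
  not perfectly structured. The measurement convention for $y$ on
  deformed wires — arc distance from the distal end of the hemiarch
  containing the site, along the deformed centerline — is this package's
  documented choice; contralateral sites then get near-equal $y$, which
  matches how the reference tables pair one $y$ per tooth.

What passing tests on synthetic data do **not** show: real arches are not
symmetric parametric curves, real bracket sites carry torque and angulation
prescriptions, and a real wire interacts with bracket slots through
clearance and friction. The generators validate the pipeline's mechanics
and bookkeeping, not clinical predictions.

## The tissue solver and its verification

`solve_elasticity()` assembles constant-strain tet4 elasticity with
per-region isotropic materials (defaults: enamel teeth, bone block,
Ni-Cr bracket pads), supports prescribed-displacement boundaries, and
derives per-element von Mises stress
$\sigma_v = \sqrt{((\sigma_1-\sigma_2)^2 + (\sigma_2-\sigma_3)^2 +
(\sigma_3-\sigma_1)^2)/2}$, a von Mises equivalent strain (computed from
principal strains and scaled by $1/(1+\nu)$, so a uniaxial state reports
its axial strain), and strain energy $\tfrac12\int \sigma : \varepsilon\,dV$
converted to joules. The reference study's result maps were computed on an
unpublished patient mesh, so their numeric maxima are not reproducible
here by construction; the module instead demonstrates the same pipeline
stage with verifiable physics:

* constant-strain patch test to machine precision,
* global equilibrium and the energy identity $U = \tfrac12 u^\top f$ to
  $10^{-8}$ relative,
* a uniaxial bar against $\sigma = F/A$ and $u = FL/(EA)$ to 2%, with the
  error decreasing monotonically under refinement,
* linearity (double the forces: double the displacements, quadruple the
  energy).

Tet4 elements are stiffness-biased; mesh density (`cell_size`) is the
accuracy knob and the radius-ratio audit (`mesh_quality()`) guards
against slivers. Units are mm–N–MPa internally; displacement maps are mm,
stresses MPa, energies J.

## Problem sizes and defaults

The package's own test and example runs use desk-scale sizes chosen to
exercise every code path at full numeric fidelity: wires of 60–152 mm at
1–2 mm beam elements (about 100–700 DOF, dense symmetric solves), and
tissue blocks of a few thousand tet4 elements (sparse Cholesky). The
calibration grid defaults to the reference protocol: stations
$z \in \{10, 20, 30, 40, 50, \text{mid}\}$ and eleven forces from 0.1 to
10 N; the mid station is half the trimmed length. Tolerances are stated
per quantity: $10^{-9}$ relative for solver-level identities, $10^{-6}$
for values read back from 6-significant-figure text, 1% for reproducing
published force rows.

## End to end

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1, out_dir = "run1")
res <- run_pipeline(cfg)
res$summary
```

Every stage checkpoints plain-text artifacts (wire CSV, site table,
calibration table, law JSON, force table, VTK field maps, JSON report),
and an identical configuration reproduces identical files.

## Known limitations

* Nitinol superelasticity and phase transformation are out of scope; the
  wire is linear isotropic, as in the reference calibration data.
* No wire–bracket contact, friction, or slot clearance.
* No periodontal ligament: teeth bond rigidly to bone in the synthetic
  model, so absolute tissue numbers are qualitative.
* Exact interpolation through seven nodes is the model — there is no
  least-squares smoothing, and the high-degree polynomial's oscillation
  and extrapolation behavior is inherited by design and flagged at use.
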
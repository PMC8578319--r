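---
title: "Ventricular wall mechanics and periventricular lesion markers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventricular wall mechanics and periventricular lesion markers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventmech)
```

# The model

`ventmech` asks a mechanical question about lesion formation: what loading
state do the ependymal cells lining the lateral-ventricle wall experience
during peak hemodynamic pressurization, and where along the wall is it
worst? The package answers it on synthetic 2D subjects with a quasistatic,
plane-strain, finite-strain boundary-value problem.

## Constitutive model

Brain tissue is modelled as a nearly incompressible one-term Ogden solid.
With the deformation gradient split $F = J^{1/3}\bar F$, $J = \det F$,
isochoric right Cauchy–Green tensor $\bar C = \bar F^T \bar F$, and
isochoric principal stretches $\bar\lambda_i$, the strain energy density
is

$$\Psi \;=\; \frac{\mu}{2}\bigl[\bar\lambda_1^2 + \bar\lambda_2^2 +
\bar\lambda_3^2 - 3\bigr] \;+\; \frac{\kappa}{4}\bigl[J^2 - 1 -
2\log J\bigr].$$

Because the isochoric stretches enter squared, this is the $\alpha = 2$
member of the Ogden family — an isochoric neo-Hookean term plus a
volumetric penalty — which keeps the stress and consistent tangent
available in closed form (`ogden_stress()`, `ogden_tangent()`; both are
verified against central finite differences of $\Psi$ in the test suite).

Default moduli (kPa): white matter $\mu = 0.68$, $\kappa = 6.6$; gray
matter $\mu = 0.34$, $\kappa = 3.3$. These encode a white/gray stiffness
ratio of 2 and a Poisson ratio of 0.45 — stiff enough volumetrically to be
*nearly* incompressible but far enough from the incompressible limit that
displacement-based linear triangles do not lock (the Lamé benchmark and
the mesh-convergence check in `tests/testthat/test-acceptance.R` guard
this choice). The CSF layer is an ultrasoft compressible solid with
$E = 0.1$ kPa, $\nu = 0.3$, converted to $(\mu, \kappa)$ so a single
material routine serves all regions; it exists to transmit the skull
constraint softly, not to model fluid dynamics.

## Loads and boundary conditions

Two follower pressures (normal to the *deforming* surface) represent peak
hemodynamic loading: 20 Pa (0.15 mmHg) on the ventricular wall and 1 Pa
on the outer gray matter surface, consistent with subarachnoid pressure
being 10–20 % of ventricular pressure. The outer CSF periphery (the
skull, orders of magnitude stiffer than tissue) is fixed.

Two modelling decisions here were genuinely open:

* **The cavity is not meshed.** The ventricle is treated as a pressurized
  void: pressure arrows act on the wall itself and the cavity is free to
  change shape and volume. The alternative reading — filling the cavity
  with the CSF surrogate — can be emulated by adding a cavity region with
  CSF material, but the loaded-void reading matches a pressure boundary
  condition drawn on the wall and avoids an artificial cavity stiffness.
* **The subarachnoid pressure is applied single-sided.** A "pressurized
  infinitesimal fluid film" at the gray/CSF interface would push both
  faces apart; on a conforming mesh both faces share the same nodes, so
  equal-and-opposite tractions cancel identically, and slitting the mesh
  would leave the brain attached to nothing (a singular pure-Neumann
  problem). The package therefore applies the film's action on the brain
  only: a follower traction pushing the cortex inward, carried to the
  skull by the meshed CSF layer. At 1 Pa against kPa-scale moduli its
  effect is small either way.

## Discretization and solver

Three-node linear triangles with one-point quadrature (exact for P1, where
$F$ is elementwise constant). The nonlinear system is solved with Newton's
method using the analytic consistent tangent plus the follower-load
stiffness, a backtracking line search, convergence at relative residual
$10^{-9}$, and automatic load stepping (5, then 10 uniform increments)
only if the full-step solve diverges. The solver contains no randomness.

Verification, all in the test suite: zero load gives exactly zero
displacement; affine fields are reproduced exactly; the assembled internal
force equals the finite-difference gradient of the total strain energy; a
two-region patch test yields a constant state to $10^{-10}$; small-load
displacements are linear in pressure to 1 %; a thick-walled annulus under
small internal pressure matches the plane-strain Lamé closed form within
2 %; the peak wall stretch changes by less than 1 % between the production
mesh and its uniform refinement by two.

# Mechanomarkers

Reference wall directions come from a Laplace ("temperature") problem on
the white and gray matter: Dirichlet values 1.0 on the ventricular wall,
0.2 on the gray/white interface, 0.0 on the gray/CSF interface. The unit
steepest-descent direction at the wall is the reference normal $n_0$
(oriented outward from the cavity), and $t_0$ is $n_0$ rotated by +90°,
aligned with the counter-clockwise wall traversal. Nodal gradients are
recovered by *angle-weighted* averaging of element gradients: on the
annulus oracle this roughly halves the direction error relative to
area weighting at the wall (about 0.6° versus 1.1° at production
resolution), and nothing in the construction depends on the specific
consistent recovery used.

Ependymal tension and compression are the projections
$\lambda_t = \sqrt{t_0 \cdot C\, t_0}$ and
$\lambda_c = \sqrt{n_0 \cdot C\, n_0}$, with $C$ averaged to wall nodes
from the adjacent white-matter elements only (the ependyma belongs to the
tissue side of the wall). The wall path starts at the node nearest the
midpoint between the two posterior horn tips and runs counter-clockwise,
so the four tension peaks appear in the order posterior, anterior,
anterior, posterior (labels A–D). Ties in peak height break towards
smaller arclength, making reports deterministic.

**The 10 % rule is applied to excess stretch.** Horn radius is measured by
the exact circumcircle through the tension peak and the two flanking
points where tension "has dropped to 10 % of the maximum". Read literally
on raw stretch this is unsatisfiable: $\lambda_t$ is bounded below by
about 1, and 10 % of a peak near 1.07 would be 0.107. The package
therefore applies the rule to the excess $\lambda_t - 1$: flanks are where
the excess first falls to 10 % of the peak excess (linearly interpolated
between wall nodes), and the same convention defines the
elevated-stretch wall fraction (total arclength with excess above 10 % of
the global peak excess, divided by total wall length). This is the single
most consequential interpretation in the package and is deliberately kept
identical across both markers.

A consequence worth knowing: the fitted horn radius is *not* the
geometric tip radius. The stretch concentration at a tip decays over a
few tip radii, so the 10 %-drop flanks land beyond the tip arc and the
circumcircle is systematically larger than the arc (by roughly a factor
2–3 across the synthetic sweep). The marker remains strictly increasing
in tip radius and strongly correlated with it — it is a monotone proxy,
exactly as useful for the radius–stretch relationships, and this is what
the tests assert.

# The synthetic subject generator

Real lateral ventricles are paired; the wall-profile semantics, however,
need one closed traversal visiting all four horns. The generator therefore
builds a single connected butterfly: two wings joined by a thin septal
channel (default gap 3 mm), preserving the A–B–C–D wall ordering without
modelling the septum pellucidum as a separate structure. The four horn
tips are exact circular arcs (anterior 2.5 mm, posterior 3 mm by default,
within the 1–5 mm span used for the radius sweep), discretized with at
least 32 segments so arc-fitting error is negligible against the radius
differences under study. The cavity (default half-extent 22 × 30 mm) is
nested in white matter, a 4 mm gray matter rim (cortical ellipse 55 × 65
mm) and a 4 mm CSF layer. Geometry is deterministic; the seed touches
image noise only.

The FLAIR surrogate is a single 2D slice at 0.7 mm pixels: unit tissue
intensity, CSF at 0.25, planted lesions at $1 + c$ (default contrast
$c = 0.6$) with Gaussian noise (default sd 0.08). Default lesions are
periventricular caps: one disk of radius 3.5 mm per horn, centred half a
radius outward of the tip apex so the cap straddles the wall — chosen so
that roughly 4 of the 30 equidistant wall sample points fall adjacent to
lesions, a positive fraction comparable to the reference wall-sampling
analysis (41 of 240). A septum surrogate — a bright strip crossing the
septal channel, labelled as brain tissue but bordered almost entirely by
ventricular CSF — is always planted to exercise the > 50 % CSF-adjacency
pruning rule.

What the generator does *not* emulate: 3D anatomy and partial-volume
averaging over 4 mm slices, bias fields (uniformity artifacts), intensity
nonstationarity across tissue, irregular lesion shapes, and the deep-WMH
phenotype. Passing tests therefore show the pipeline implements its rules
correctly on clean planted signal; they do not certify segmentation
accuracy on clinical FLAIR.

# Segmentation conventions

$\Omega$ (the brain mask) comes from the label image (white + gray
matter) rather than an intensity heuristic — the reference workflow's
whole-brain masking algorithm is proprietary and unspecified, and
inventing one would blur what is being tested. $\sigma$ uses the
population convention (1/N), with a `sd_type` switch; the threshold is a
strict inequality, so a constant image segments to nothing. Components
use 4-connectivity (face adjacency) by default with an 8-connectivity
option; a component's boundary is its set of face-adjacent exterior
pixels, counted as pixels (not incidences), and a component is removed
when more than half of those pixels are CSF. The brute-force flood-fill
oracle in the tests pins all of these conventions on 100 random images.

# Statistics conventions

Pearson correlations use the t-based two-sided p-value on $n-2$ degrees
of freedom. Table summaries use the sample standard deviation (1/(n−1)),
which reproduces the printed spreads of the embedded table. The
wall-sampling comparison uses Welch's unequal-variance t-test with
Welch–Satterthwaite degrees of freedom: with groups as unbalanced as
41 vs 199, pooled degrees of freedom (238) are incompatible with the
reported df of about 49, while Welch df are. Wall points are labelled
lesion-positive when the nearest wall node lies within 1.5 mm (about two
pixels) of a segmented lesion pixel centre — the "abuts a lesion" rule
made concrete.

# Numerical choices and degenerate inputs

* **Meshing.** Delaunay triangulation of seeded points (via `interp`),
  with: shared boundary discretizations so regions conform exactly; a
  graded size field (0.35× the background edge length at the wall,
  growing linearly over 12 mm); additional tip refinement at about one
  fifth of each horn radius, scaled with the global target so
  convergence studies refine the tips too; hex-grid interior seeding
  thinned to the local size; smoothing sweeps; a sliver-dissolving pass
  targeting a 25° minimum-angle floor; and conformity repair that deletes
  interior seeds blocking a required boundary segment. A tiny
  deterministic jitter is applied to the coordinates handed to the
  triangulator only — exact collinear runs (straight tangent lines) and
  cocircular points (arcs, hex grids) are degenerate for Delaunay codes —
  and zero-area slivers that the jitter can induce on collinear runs are
  removed in exact coordinates.
* **Determinism.** All meshing randomness runs under fixed internal
  seeds with the caller's RNG state restored, so a configuration plus the
  code version fully determines every output; `run_subject()` records a
  fingerprint over the headline outputs to detect nondeterminism
  regressions.
* **Degenerate inputs.** Unloaded profiles ($\lambda_t \equiv 1$) refuse
  peak detection with a clear error and report a zero elevated fraction;
  collinear circle-fit points raise an error rather than an infinite
  radius; empty Dirichlet sets and empty brain masks are named in errors;
  element inversion reports the offending elements.
* **Problem sizes.** The production configuration uses a 2.2 mm
  background edge length (about 9000 triangles, 0.77 mm wall spacing);
  the convergence check refines to 1.1 mm (about 38 000 triangles); the
  radius sweep runs five subjects and the sensitivity sweep nine solves
  on one mesh. A full default subject runs in seconds on one CPU.

# Sensitivity behaviour

Across pressure scales 0.5–10× the peak tension grows strictly but
sub-proportionally (the material stiffens), the compression minimum
deepens, and the peak locations do not move by even one wall edge — the
horns stay the loaded sites regardless of load magnitude. Stiffness
scaling of white matter from 25 % to 400 % moves the peak tension the
opposite way: softening raises cell load, which is what makes
degeneration-driven softening a plausible positive-feedback ingredient.
These directions, and the radius-sweep monotonicities with their
reciprocal/linear fits, are asserted by the acceptance tests; the exact
factors for any given run are recomputed by `scripts/acceptance.R`, and
subject-specific values from other geometries are not asserted as
equalities.

# Known limitations

The model is 2D plane-strain on one slice: out-of-plane ventricular
motion and pulsatile CSF dynamics are out of scope, as is any damage or
growth law coupling overstretch to tissue change (the markers quantify
the loading state only). The synthetic cavity is one connected structure,
so inter-hemispheric asymmetry is not represented. The fitted horn radius
is a monotone proxy for tip radius, not an unbiased estimate of it. Real
FLAIR segmentation would additionally need uniformity correction and a
brain-mask heuristic, both deliberately excluded here.
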
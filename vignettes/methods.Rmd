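---
title: "Modeling the microenvironment of a dual-chamber osteochondral perfusion bioreactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the microenvironment of a dual-chamber osteochondral perfusion bioreactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system being modeled

Osteochondral constructs couple two tissues with incompatible culture
requirements: cartilage prefers near-quiescent, low-shear conditions,
bone benefits from perfusion-induced shear. A dual-chamber perfusion
bioreactor addresses this by perfusing chondrogenic medium over the
chondral half of a bilayered scaffold and osteogenic medium over the
osseous half, with the scaffold itself as the only communication
between the chambers.

`ocperfusion` simulates the steady microenvironment of such a system:

* a parametric, additively-manufactured PLA lattice — a fine 500 µm
  strut / 500 µm spacing chondral mesh whose pores are filled with
  collagen hydrogel, a coarse 1000 µm strut osseous mesh, and two
  close-packed separator layers — inside a cylindrical two-chamber
  vessel;
* steady creeping flow of the two media with the collagen treated as a
  Brinkman porous medium;
* advection–diffusion of a normalized media tracer to quantify how much
  of each medium leaks into the other chamber;
* fluid-induced shear stress (FSS) on the strut surfaces, the quantity
  the osteo/chondrogenic literature thresholds are written in;
* a synthetic micro-CT pathway that emulates the difference between the
  CAD geometry and the as-manufactured part, so that the sensitivity of
  all of the above to printing artifacts can be studied without a
  scanner.

## Geometry and its open parameters

The scaffold envelope (15 mm diameter × 10 mm height), strut diameters,
spacings and the number of separator layers are taken as given. Two
geometric quantities are *not* published and are set here as documented
assumptions:

* **Section heights.** With a 500 µm print layer and the total height
  fixed at 10 mm, the package uses 4 mm of osseous lattice (4 strut
  layers of 1000 µm), a 1 mm separator (2 layers of 500 µm), and 5 mm
  of chondral lattice (10 layers of 500 µm) — an exact fill. Both
  heights are `scaffoldSpec()` parameters.
* **Chamber and ports.** The chamber is cylindrical with 1 mm diametral
  clearance around the scaffold, 5 mm plenum above and below, and two
  inlet plus two outlet ports of 1.02 mm bore per chamber on opposing
  sides (matching the pump tubing). Port centres sit level with the
  mid-height of the scaffold section each chamber perfuses: the
  reported flow pattern places the velocity maxima right at the inlets
  of the scaffold sections, which requires the cross-flow to pass the
  lattice rather than short-circuit through the plenum. All of this is
  configurable in `chamberSpec()`.

A third choice concerns the separator: perfectly touching close-packed
struts would seal the chambers from each other completely, which would
contradict the observed media mixing. The in-layer gap between
separator struts is therefore a first-class parameter
(`separator_gap`, default 20 µm).

The lattice is voxelized onto a uniform, cell-centred, isotropic grid
(`voxelize()`), each voxel labeled WALL, LUMEN, SOLID, or POROUS and
tagged with its axial layer. The z axis points from the osseous
(bottom) to the chondral (top) section — the culture orientation, which
all reported results use; the print orientation is inverted relative to
this but is irrelevant to the physics.

## Flow model

Flow is solved with one unified Brinkman momentum equation over the
whole cavity,

$$\mu \nabla^2 \mathbf{u} - \nabla p - \frac{\mu}{k(\mathbf{x})}\mathbf{u} = 0,
\qquad \nabla\cdot\mathbf{u} = 0,$$

with the drag term switched off in the lumen, $k = 10^{-12}\,
\mathrm{m^2}$ in the collagen, and a vanishing penalization
permeability $k = 10^{-18}\,\mathrm{m^2}$ inside PLA voxels. The
penalization turns the struts into part of the same linear system, so
stair-stepped solid boundaries need no special treatment; the residual
velocity deep inside struts is bounded in the test suite at below
$10^{-4}$ of the inlet velocity.

Inertia is omitted: at 0.02 ml/min through 1.02 mm tubing the inlet
velocity is 0.41 mm/s and the Reynolds number is about 0.4, so the
creeping-flow system is linear in the flow rate (also verified by the
suite). An optional explicit Picard correction (`picard` argument of
`solveFlow()`) re-adds the convective term for verification at higher
rates; it is off by default.

Boundary conditions: a parabolic velocity profile over each inlet port
disc, discretely rescaled so the imposed flux equals the prescribed
chamber flow rate exactly; fixed pressure at outlets; no-slip
everywhere else. The per-chamber flow rate (default 0.02 ml/min) is
interpreted as the chamber total and split equally over that chamber's
inlet ports, since one pump line feeds each chamber.

Discretization is a staggered (MAC) finite-volume scheme: velocities on
faces, pressure in cells, mirror ghosts for tangential no-slip walls.
The saddle-point system is solved monolithically through its pressure
Schur complement: the three SPD momentum blocks are factored once with
a sparse Cholesky (CHOLMOD via the Matrix package) and conjugate
gradients run on the Schur complement with the SIMPLE-type
preconditioner $G^{T}\,\mathrm{diag}(A)^{-1}G$, which is nearly exact
in drag-dominated (penalized and porous) regions and standard in open
flow. The default relative continuity tolerance is $10^{-10}$ —
tighter than the $10^{-8}$ one would pick for the flow alone, because
the transport stage inherits the face fluxes and the discrete maximum
principle of the tracer is only as good as the divergence of the
advecting field.

Velocities reported in collagen voxels are superficial (Darcy)
velocities; `velocityStats(..., interstitial = TRUE)` divides by the
collagen porosity (0.90) where pore-scale velocity is wanted.

## Media transport and mixing

The steady tracer satisfies
$\nabla\cdot(\mathbf{u}c) = \nabla\cdot(D_{\mathrm{eff}}\nabla c)$ with
$c = 1$ at the top (chondrogenic) inlets and $c = 0$ at the bottom
(osteogenic) inlets, zero diffusive flux at outlets, and zero flux at
walls. $D = 2.907\times10^{-9}\,\mathrm{m^2/s}$ in free medium; inside
the collagen the effective diffusivity is reduced by simple porosity
scaling, $D_{\mathrm{eff}} = \varphi D$ with $\varphi = 0.9$ (the
source model states one $D$ and is silent on a porous reduction; the
factor is configurable). Penalized solid voxels participate with a
vanishing diffusivity so that the advective fluxes of the penalized
flow field remain divergence-consistent — this is what lets the
discrete maximum principle hold to round-off rather than to the
penalization leakage scale.

Advection uses the hybrid (Spalding) scheme: central differencing on
faces whose cell Péclet number is below 2, first-order upwinding
elsewhere. Below Pe = 2 the central coefficients still form an
M-matrix, so the hybrid operator is an M-matrix everywhere and the
tracer cannot over- or undershoot its inlet bounds. This is the
direct-assembly equivalent of deferred correction toward central
differencing in the low-Péclet regions, chosen because it needs a
single linear solve. At the default operating point most of the domain
sits below Pe = 1 (`pecletReport()` quantifies this), where the scheme
is second order. The nonsymmetric system is solved by BiCGSTAB after
symmetric Jacobi scaling, preconditioned with a Cholesky factorization
of the operator's symmetric part.

Outlet mixing is flux-weighted: the mixing fraction of the top chamber
is $1 - \langle c\rangle$ over its outlet faces (weighted by the
outflow through each face), and $\langle c\rangle$ for the bottom
chamber. The source reports mixing "at the outlets" without defining
the average; flux weighting is what a downstream reservoir actually
receives.

## Fluid-induced shear stress

The scaffold is rigid (the solid is modeled with a fixed-volume
constraint, i.e. it does not deform), so the traction the struts and
the cells on them experience is available from the fluid side. For
every SOLID voxel with a fluid neighbour, the surface normal is taken
from the gradient of a Gaussian-smoothed solid indicator; the
tangential velocity magnitude is sampled by trilinear interpolation at
one and two voxel spacings from the wall along the normal, and

$$\tau = \mu\,\frac{4u_t(h) - u_t(2h)}{2h}$$

gives a one-sided estimate that is exact for linear and quadratic
near-wall profiles (plane Couette is recovered to round-off; a
Poiseuille tube at 24 cells across the diameter is recovered to within
a few percent — both in the test suite). Statistics are reported in
mPa per scaffold layer, together with the fraction of strut surface
below 1 mPa.

Layer statistics (velocity, FSS, concentration) are taken over the
scaffold's bounding cylinder per axial band; plenum voxels are excluded
and reported separately (`extras` of the report), since near-inlet
chamber maxima and in-scaffold means answer different questions.

## The synthetic micro-CT pathway

The generator emulates the chain *as-manufactured part → tomographic
scan → smoothing → automatic segmentation* that produces an image-based
model of a printed scaffold:

* **Printing artifacts** (`applyPrintArtifacts()`): per-strut
  multiplicative diameter error (truncated-normal, redrawn if a draw is
  non-positive), vertical flattening (sag) of the deposited strands,
  and a smooth two-sinusoid along-strut radius modulation for surface
  roughness. Defaults — mean diameter scale 1.15, SD 0.03, sag 0.10,
  roughness 25 µm — describe a fused-deposition print with moderate
  over-extrusion, whose net effect is a denser-than-CAD lattice: the
  direction of change reported for manufactured-vs-CAD osteochondral
  scaffolds. The whole pathway is a pure function of its seed.
* **Rendering** (`renderGrayscale()`): solid → high intensity,
  everything else → background. Collagen is radiolucent and renders as
  background — the segmentation cannot see it, exactly as a real scan
  cannot; the segmented grid re-inserts collagen into the chondral
  pores from the specification, mirroring how the image-based model is
  assembled in practice. Partial volume is a Gaussian point-spread
  (default half a voxel), detector noise is additive Gaussian (default
  SD 10 % of contrast), and a smooth radial multiplicative bias mimics
  residual beam hardening.
* **Smoothing** (`smoothBilateral()`): joint spatial/range Gaussian
  over a spherical window of three spatial sigmas — denoises while
  keeping the solid/background edge; in the infinite-range limit it
  reduces to plain Gaussian smoothing (a test pins this).
* **Segmentation** (`autoThreshold()`): global Otsu threshold on the
  intensity histogram. "Automatic thresholding" is underspecified in
  the source; Otsu is reproducible and parameter-free, which is why it
  was chosen. Wall, layer tags and collagen are reinstated from the
  reference grid.

What the generator does **not** emulate: projection physics (no Radon
transform, ring or metal artifacts), scanner-specific noise spectra,
strut delamination or missing material, and the 7.9 µm resolution of a
real scan — the synthetic default is 50 µm to stay desk-scale. Passing
round-trip tests therefore demonstrates the internal consistency of
the pathway (segmentation recovers what was rendered, artifacts move
porosity the right way), not fidelity to any particular scanner.

## Numerical choices and problem sizes

* Voxel resolution is the accuracy dial. The solver oracles run at
  32–64 cells across a channel; the full-chamber runs in the test
  suite and the acceptance script use 500 µm voxels (a 66 × 66 × 82
  grid, about 10^5 momentum unknowns), which resolves the osseous
  lattice coarsely and the chondral lattice only marginally — chosen so
  a paired CAD/manufactured run completes in minutes on one CPU. The
  synthetic micro-CT checks run at the 50 µm default on a quarter
  scaffold. Conclusions drawn at 500 µm are directional (signs of
  CAD-vs-manufactured changes, mixing ordering), not absolute values.
* Flow: continuity tolerance $10^{-10}$ (relative), iteration cap
  10 000; Cholesky-factored momentum blocks; zero-velocity initial
  guess. Degenerate inputs (no ports, sealed domains, non-converged
  inputs to downstream stages) raise errors rather than propagate
  silently.
* Transport: BiCGSTAB tolerance $10^{-10}$ after Jacobi scaling;
  Dirichlet inlet faces enter through both the advective and the
  half-cell diffusive flux.
* Ties and boundaries: the regime classifier uses strict inequalities
  at thresholds (a layer exactly at the detachment velocity is not
  flagged); Otsu takes the first histogram maximum on ties.
* Determinism: every stochastic step (artifact draws, rendering noise)
  flows from explicit integer seeds; two runs with the same config and
  seed are bit-identical.

## What the absolute numbers can and cannot reproduce

The published finite-element results for this system depend on the
actual bioreactor chamber drawing (never published) and on the real
micro-CT scan of the printed scaffold (not deposited). The package
therefore targets the *structure* of those results — per-layer
statistics, flux-weighted mixing, CAD-vs-manufactured signed changes —
and verifies its solvers against closed-form oracles instead: plane
Poiseuille, square-duct series, Darcy slab, Poiseuille-tube wall
shear, diffusion slab, and the 1-D advection–diffusion boundary layer.
Qualitative mirrors of the published comparison (a denser manufactured
osseous mesh raises its mean interstitial velocity; chondral media
supply is insensitive; most foreign medium ends up in the osteogenic
chamber) are asserted as directions, with magnitudes recorded by the
acceptance script.

## Known limitations

* The voxel solver is first-order accurate at stair-stepped boundaries;
  FSS maxima on coarse lattices are systematically smoothed relative to
  a body-fitted mesh.
* No transient effects: media changes every few days, cell growth,
  scaffold degradation and fluid–structure interaction are all outside
  the model.
* The collagen is homogeneous ($k$, $\varphi$ constant); real gels are
  not.
* The regime thresholds encode a literature that disagrees with itself
  about effective osteogenic shear magnitudes; the band is configurable
  and verdicts carry their citations.
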
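---
title: "Gray-Scott morphogenesis on a growing surface: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-Scott morphogenesis on a growing surface: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticofold)
```

## The model

`corticofold` simulates cortical gyrification as the interplay of two
processes on a closed triangulated surface $S(t)$:

1. **Morphogen chemistry.** Two diffusing species react on the surface
   following Gray-Scott kinetics: a substrate $u$, fed at rate $F$ and
   consumed by cubic autocatalysis, and an autocatalyst $v$, produced by
   the same term and removed at rate $F + k$:
   $$\partial_t u = D_u \Delta_S u - u v^2 + F(1 - u), \qquad
     \partial_t v = D_v \Delta_S v + u v^2 - (F + k)\, v.$$
   Here $\Delta_S$ is the Laplace-Beltrami operator of the current
   surface. The trivial state $(u, v) = (1, 0)$ is always a fixed point;
   over a narrow wedge of the $(F, k)$ plane the system supports
   persistent spatial patterns — stripes, labyrinths, spot lattices —
   seeded from finite perturbations.

2. **Surface growth.** Each vertex moves along its outward unit normal
   at a rate proportional to a linear function $f$ of one morphogen,
   $\dot x_i = \alpha f_i\, n_i$. Because the domain carries the
   chemistry, growth feeds back: local area expansion thins
   concentrations at the rate $(1/\sqrt{g})\,\partial_t \sqrt{g}$, the
   *dilution* term, where $\sqrt{g}$ is the square root of the metric
   determinant (per triangle, exactly twice its area). We estimate it by
   a backward difference of $\sqrt{g}$ — the forward geometry is
   unknowable in this Lagrangian frame — and add it to the linear
   removal terms of both equations.

Folds are read off the geometry: the per-vertex mean curvature (sign
convention: convex/gyral positive, concave/sulcal negative) is
thresholded at zero, and the connected components of the negative set
under mesh adjacency are the sulci.

## Discretization

The chemistry is discretized with linear (P1) finite elements on the
triangulation: the mass matrix $M_{ij} = \int \phi_i \phi_j$ (per
triangle: $A/6$ diagonal, $A/12$ off-diagonal) and the stiffness matrix
$K_{ij} = \int \nabla \phi_i \cdot \nabla \phi_j$, whose per-triangle
diagonal is $A / h_i^2$ with $h_i$ the triangle height from vertex $i$
— algebraically the classic cotangent weights. Time stepping is
semi-implicit (IMEX): diffusion, the linear removal terms, the dilution
term and the lagged nonlinear coefficient $(v^n)^2$ are implicit, the
feed and the $u v^2$ production explicit,
$$\left(M + \Delta t\, D_u K + \Delta t\, \tilde M[(v^n)^2 + F + d]\right) u^{n+1}
  = M u^n + \Delta t\, F\, M \mathbf 1,$$
$$\left(M + \Delta t\, D_v K + \Delta t\, \tilde M[F + k + d]\right) v^{n+1}
  = M v^n + \Delta t\, M\!\left(u^n (v^n)^2\right),$$
with $\tilde M[w]$ the lumped (barycentric) mass scaled per vertex by
$w$. This splitting was chosen so that both system matrices are
symmetric positive definite for every admissible state — each step is
two sparse Cholesky solves with a verified relative-residual contract
(default $10^{-10}$), reusing one symbolic analysis for as long as the
connectivity is unchanged. The scheme is first-order in $\Delta t$
(observed order $\approx 1$ on a fixed mesh) and conserves
$\sum (M u)$ exactly in the pure-diffusion limit on a closed surface.

Between chemistry steps the surface deforms, the dilution field is
measured (before any topology change, so the two geometries share
connectivity), and any triangle whose area exceeds twice the initial
mean face area is split into four on its edge midpoints; a neighbor
sharing one split edge is split in two, with compatible templates for
two or three split edges, so the mesh remains a closed 2-manifold with
no T-junctions. Midpoint fields are edge-endpoint means, consistent
with P1 interpolation; midpoint subdivision is planar per face, so the
refinement changes no area.

The per-vertex mean curvature uses the discrete mean-curvature normal
$K x$: its magnitude divided by twice the vertex area gives $|H|$, its
orientation against the outward vertex normal the sign. The normalizing
area is the circumcentric (Voronoi) area implied by the cotangent
weights, which is substantially more accurate than the barycentric area
at the twelve valence-5 vertices of an icosphere (error $\sim 10^{-5}$
versus $\sim 15\%$ there); where obtuse triangles make the Voronoi area
non-positive the barycentric area substitutes.

Fields are transferred between meshes (for the temporal stability map
$A$ and the ensemble reproducibility map $S$) by smoothing both meshes
with simultaneous neighbor-averaging sweeps (default 100), projecting
the vertices radially onto the unit sphere about the centroid, and
interpolating barycentrically from the source face containing each
target direction. Indicator maps are re-binarized at $0.5$ after
transfer. This assumes the smoothed meshes are star-shaped, which holds
for the bounded deformations produced here.

## Parameters and their defaults

| parameter | default | units | role |
|---|---|---|---|
| $F$ | 0.04 | 1/time | feed rate (printed normal-regime pair) |
| $k$ | 0.06 | 1/time | kill rate |
| $D_u, D_v$ | $2\times10^{-3}$, $10^{-3}$ | length$^2$/time | diffusion, classic 2:1 ratio |
| $\Delta t$ | 1 | time | IMEX step |
| $\alpha$ | $2.5\times10^{-4}$ | length per morphogen per time | deformation gain |
| driver | $u$ | — | morphogen driving growth |
| subdivisions | 3 (642 vertices) | — | icosphere resolution |
| radius | 1 | length | initial sphere |
| horizon | 1500 | steps | default run length (4000 = full scale) |
| band half-width | 0.15 | rad | seeded great-circle line |
| band $(u, v)$ | (0.5, 0.25) | — | classic excited-seed values |
| noise amplitude | 0.1 | — | uniform white noise inside the band |

Two of these deserve explanation, because they are *resolution-matched*
rather than inherited:

**Diffusion.** The classic grid studies of Gray-Scott patterns use
$D_u = 2\times10^{-5}$ on a $2.5$-unit square at a grid spacing of
$10^{-2}$, giving a pattern wavelength near $0.1$. A unit-sphere
icosphere at subdivisions 3–4 has edge lengths of $0.15$/$0.075$ and
cannot represent that wavelength: the excited band simply decays at
every $(F, k)$. The package therefore scales both coefficients by 100
(keeping the 2:1 ratio), placing the wavelength near 1 — six to seven
mesh edges — where the discrete operator sustains the patterns. We
validated the choice against an independent, well-resolved explicit
finite-difference integration on a periodic square of equal area: at
the package's coefficients the $(0.04, 0.06)$ pattern persists
indefinitely, and $(0.05, 0.05)$ returns to homogeneity, in agreement
with the surface solver.

**Growth driver.** The package grows the *substrate-rich background*
(driver $u$): activator regions lag behind the expanding surface and
sink into folds, so the seeded activator line becomes the reproducible
main sulcus — the sulcal-root picture in which initial conditions are
the seeds of folds. We tried the opposite assignment (activator regions
bulge outward as gyri) and found two failures: folds then form as
fragmentary flanking grooves whose positions vary across noise
realizations, destroying ensemble reproducibility, and the dilution of
the growing stripes acts as extra kill exactly where the pattern lives,
making survival seed-dependent. With driver $u$ the dilution falls
mostly on the homogeneous background and is pattern-neutral.

$\alpha = 2.5\times10^{-4}$ keeps the per-step displacement far below
the mean edge length (the constructor warns above 10%) while folding
the surface within the default horizon; the in-band noise amplitude 0.1
makes pattern nucleation reliable across seeds.

## What the synthetic conditions do and do not emulate

All inputs are synthetic: a geodesic icosphere (no polar mesh artifact)
and the seeded-line initial state. The default scale — 642 vertices,
horizon 1500 — is deliberately small so that a full regime comparison,
a ten-member ensemble and the test suite run on one CPU in minutes.
Passing tests at this scale demonstrate the *mechanisms*: Turing-type
patterning on the evolving surface, dilution-coupled growth, fold
segmentation, temporal stability and ensemble reproducibility of the
main fold. They do not demonstrate full-scale cortical richness: at
this domain-to-wavelength ratio (circumference ≈ 6 wavelengths) a run
carries a handful of folds, not dozens, and two known departures from
the full-scale phenomenology remain:

- The spot regime at $(0.03, 0.06)$ is not sustainable from the thin
  seeded line at this domain size. The independent finite-difference
  oracle reproduces the same decay at matched scale for *every*
  diffusion coefficient, so this is physics of the scaled conditions,
  not a solver defect: spot nucleation requires a seed several
  wavelengths wide or a domain many wavelengths across. The package's
  phase diagram labels such runs homogeneous.
- Per-vertex ensemble coincidence saturates near 60%: realizations fold
  different longitude segments of the band, whereas the continuous deep
  main fold of a full-scale run overlaps near-perfectly. The spatial
  *concentration* of reproducibility on the band (band mean ≈ 20% vs 0%
  at the poles at $n = 10$) is robust.

## Numerical choices and degenerate inputs

- Tolerances: SPD solves at $10^{-10}$ relative residual; stiffness
  annihilates constants to $10^{-10}$; refinement preserves area to
  machine precision.
- The dilution field is zero by convention on the first step (no
  previous metric exists), and an error is raised if shrinkage is ever
  pathological enough to destroy positive-definiteness.
- Concentrations are monitored against $[0, 1] + 10^{-6}$ and a warning
  is issued on violation. With the consistent mass matrix (the default)
  the solution briefly undershoots by $\sim 10^{-4}$ near the sharp
  edges of the seeded band — P1 with consistent mass has no discrete
  maximum principle — and returns inside the bounds as the transient
  relaxes; the lumped-mass option makes the implicit matrices
  M-matrices and restores monotonicity at the cost of extra numerical
  diffusion.
- Degenerate (zero-area) faces abort geometry computation with the face
  index; non-manifold inputs are rejected at construction.
- Homogeneous equilibria: the saddle-node discriminant $F - 4(F+k)^2$
  is treated as zero within $10^{-12} F$ so that the printed pair
  $(0.04, 0.06)$, which sits exactly on the curve, reports its
  degenerate double root.
- Fold segmentation is breadth-first region growing from the
  lowest-index seed; labels are independent of seed order, and the
  implementation is cross-checked against an independent
  graph-components oracle in the tests.
- Self-intersection of the deformed surface is not detected or
  prevented, consistent with the bounded gains and horizons used.

## Known limitations

Beyond the two scale departures above: no mechanical (elastic) tissue
model, no skull constraint, no collision handling, first-order time
accuracy, and the stripes-versus-spots classifier (mean fold-component
elongation, threshold 2 in edge/$\sqrt{\text{vertices}}$ units) is
calibrated on the printed parameter pairs at the default scale —
fragmented deep folds on refined meshes can depress the elongation of
genuinely stripe-like patterns.
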
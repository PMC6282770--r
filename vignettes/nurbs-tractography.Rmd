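---
title: "Fiber tractography by rational B-spline curve fitting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber tractography by rational B-spline curve fitting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nurbstrack)
```

## The problem

Water diffusion in white matter is anisotropic: it is hindered across axon
bundles and comparatively free along them. High-angular-resolution
diffusion imaging samples the diffusion signal along many directions on a
spherical shell, from which an orientation distribution function (ODF) can
be reconstructed per voxel — a non-negative function on the sphere whose
local maxima indicate fiber axes. Tractography turns a volume of such
per-voxel orientation evidence into explicit 3-D fiber pathways.

`nurbstrack` implements a deterministic tracker that represents each
pathway as a nonuniform rational B-spline (NURBS) curve. The pipeline has
three stages:

1. **Peak extraction** — each voxel's ODF samples are reduced to a small
   matrix of unit fiber axes $v_i$ with diffusion probabilities $d_i$;
2. **Chain extraction** — starting from a seed voxel, the consecutive
   (voxel, direction) pairs along a pathway are collected across
   26-connected neighbors under distance, angle, length and anisotropy
   constraints;
3. **Curve fitting** — the chain is converted into NURBS control points
   and weights and the fitted curve is sampled into a polyline.

A fixed-step multidirectional streamline tracker is included as a
baseline, and an evaluation module computes local (spatial / tangent /
curvature symmetric RMSE) and global (valid / invalid / no connection)
tractogram metrics against ground truth.

## Peak extraction

The sampling shell is stored with its convex-hull adjacency (for unit
vectors the hull is the spherical Delaunay triangulation). A vertex is
retained as a fiber axis when its value is a **strict** local maximum over
its hull neighborhood and **strictly** above the voxel's mean ODF value;
plateaus therefore yield no peak, which keeps degenerate inputs
deterministic. Mean-thresholding is per voxel: the threshold adapts to each
voxel's overall ODF level, which is what makes it a cheap but effective
spurious-peak filter.

ODFs are axial ($\psi(v) = \psi(-v)$), so maxima come in antipodal pairs;
pairs within 5° axial angle are merged, keeping the larger value. The
bundled `fibonacci_sphere()` scheme is built antipodally symmetric (a
hemispheric Fibonacci lattice plus its mirror image) precisely so that the
two maxima of one axis are exact antipodes — with an asymmetric scheme the
two hemispheric maxima can sit a full vertex spacing apart and would
survive as duplicate axes. Retained values are normalized to per-voxel
probabilities $d_i$ summing to one.

When no tensor-derived FA map is supplied, the tracker needs some
anisotropy scalar for its stop rule; the standard ODF-based generalized
FA,
$\mathrm{GFA} = \sqrt{N\sum_i(\psi_i-\bar\psi)^2 / ((N-1)\sum_i\psi_i^2)}$,
is computed per voxel. It is scale-invariant and zero for isotropic
profiles.

## Chain extraction

Diffusion directions are taken to pass through voxel centers. From the
current (voxel, direction), candidate continuations are the 26-neighbors
that are unvisited, lie in the forward hemisphere (strictly positive inner
product of the center offset with the heading — this prevents immediate
backtracking), are inside the white-matter mask, have FA at or above
`FA_th`, and whose centers lie within `d_th` of the line through the
current center along the current direction. Among the admissible
directions of the surviving voxels (axial angle to the heading at most
`theta_th`), the tracker picks the voxel whose center the direction line
passes **nearest**, breaking ties by smaller axial angle, then larger
$d_i$, then lexicographic voxel index.

The distance-first ranking is the design decision that separates this
scheme from FACT-style tracking: FACT jumps to whichever neighbor the ray
exits into, which on coarse grids can favor a diagonal neighbor whose
center is far off the direction line. Ranking by line-to-center distance
follows the direction line itself. We also evaluated the alternative of
ranking by axial angle first: on curved bundles it produces long straight
runs that hug the outer voxel row of the bundle (the nearest on-row voxel
almost always has the most similar direction), visibly flattening arcs,
so the distance-first rule is used throughout.

Angle comparisons are axial, $\min(\theta, 180°-\theta)$, because ODF
maxima carry no sign; each accepted direction is polarity-flipped to keep
propagating forward. Accepted voxels enter a visited set — the geometric
constraints alone do not preclude cycles on noisy fields.

Chains are launched bidirectionally: one chain along $+v_i$ and one along
$-v_i$ for every seed-voxel axis, spliced at the seed. Each side receives
half the length budget `L_th`, so the combined chain respects the fiber
length threshold symmetrically regardless of where the seed sits on the
bundle. The cost is that a seed near one end of a long bundle cannot
spend its unused backward budget on the forward side; we prefer the
invariant (combined length ≤ `L_th`, always) over the marginal extra
coverage.

### Tunable parameters

| Parameter  | Meaning                                   | Unit | Default |
|------------|-------------------------------------------|------|---------|
| `theta_th` | max axial angle between consecutive steps | deg  | 60      |
| `L_th`     | max fiber length                          | mm   | 70      |
| `FA_th`    | min fractional anisotropy                 | —    | 0.15    |
| `d_th`     | max line-to-neighbor-center distance      | mm   | half the voxel diagonal |
| `step`     | output sampling step along pathways       | mm   | 0.5     |

The angle/length/FA defaults are the operating point used in the
evaluation experiments this package reproduces. `d_th`'s default (half
the voxel diagonal) admits exactly those neighbors whose centers the
direction line passes nearer than any other voxel's center; it scales with
the grid. `FA_th` is deliberately permissive — FA drops below ~0.2 in
crossing-fiber voxels, so an aggressive threshold would truncate chains at
crossings.

## NURBS fitting

A NURBS curve of degree $p$ with control points $P_i$, positive weights
$w_i$ and knot vector $U$ is
$C(u) = \sum_i N_{i,p}(u)\,w_i P_i \,/\, \sum_i N_{i,p}(u)\,w_i$.
Curves are cubic by default — the standard choice; higher orders buy
numerical trouble rather than fidelity — with the degree reduced to
$n_{\mathrm{ctrl}}-1$ for short chains and chains yielding fewer than two
control points dropped. Knot vectors are clamped (end knots repeated
$p+1$ times, forcing endpoint interpolation), normalized to $[0,1]$, and
evenly spaced inside.

Control points come from the chain in two modes:

* **NURBS-T (tangent-consistent)**: per node, the entry intersection of
  the node's direction line with the voxel box, the voxel center, and the
  exit intersection. The three are collinear along the diffusion
  direction, so the control polygon runs parallel to the fiber axis at
  every center — realizing the premise that a pathway's local tangent
  agrees with the local diffusion orientation without derivative-
  constrained fitting.
* **NURBS-G (general)**: entry and exit intersections only.

Consecutive nodes share one boundary crossing: the exit point of node $k$
and the entry point of node $k+1$ are two estimates of it, and are unified
into their midpoint (for exactly collinear chains they coincide on the
shared facet, and the midpoint *is* that point). Keeping both estimates
would make the control polygon backtrack wherever consecutive direction
lines disagree, and the fitted curve oscillates. One control point per
crossing is also what the two-dimensional construction diagrams of both
modes depict.

Weights are derived from the diffusion probabilities: every control point
inherits the $d_i$ of its source node, a unified crossing point gets the
average $(d_k+d_{k+1})/2$, and the vector is normalized so its maximum is
one — the absolute scale of rational weights does not affect the curve,
only their ratios do. With all $d_i$ equal the curve reduces exactly to
the non-rational B-spline.

Fitted curves are discretized by chord-length reparameterization on a
parameter grid refined by doubling until the total length converges within
$10^{-4}\cdot$`step`; first and last output points are the exact curve
endpoints.

## Evaluation metrics

Local metrics are symmetric RMSEs over matched closest points
(point-to-segment matching on the resampled polylines, which is robust to
different sampling densities): squared Euclidean distance (spatial,
mm), squared axial angle between finite-difference tangents (tangent,
radians), and squared curvature difference (curve, 1/mm), with discrete
curvature taken as the inverse circumradius of consecutive vertex triples.
Each metric is symmetrized as the square root of the mean of the two
directed mean-square errors.

Global metrics classify each pathway by its endpoints: both endpoints in
the two ROIs of one bundle with the whole course inside the white-matter
mask is a *valid connection*; endpoints in ROIs of different bundles an
*invalid connection*; everything else *no connection*. The three classes
partition the pathway set, so VC+IC+NC = 100% by construction (published
tables using these names sometimes exceed 100% under unstated
conventions; we report a partition and note the discrepancy rather than
imitating it). VB counts true bundles reached by at least one valid
connection, IB distinct wrong ROI pairs.

Two boundary conventions matter here. Voxels are half-open boxes (a
point on a shared facet belongs to the larger-index voxel) with the
grid's outer surface closed, so facet points of boundary voxels remain
addressable. And endpoints are attributed to the voxel the pathway
*reaches them through* — the point is nudged $10^{-6}$ of the adjacent
segment inward before lookup — because NURBS pathways end on voxel facets
by construction, and the raw half-open rule would systematically assign
such endpoints to the voxel beyond the mask. Mask containment is tested
at segment midpoints for the same reason.

## The synthetic phantom

`phantom_spec()` describes grids carrying straight, arc, helix, crossing
or bent bundles as constant-speed analytic curves, placed centrally with a
one-voxel margin and anchored on the center voxel's center so straight
bundles run through voxel-center rows (on an even-dimensioned grid the
geometric center lies exactly on voxel boundaries, which would make the
rasterized bundle ambiguous between two rows).

`generate_field()` gives every voxel the curve passes within half a voxel
diagonal of its center — the voxels the curve actually threads, with no
overhang past the curve ends — the curve's unit tangent at the
(numerically refined) nearest point, with probability proportional to
proximity and normalized per voxel; crossing voxels carry both axes. The
white-matter mask and the high-FA region are the wider tube within one
full voxel diagonal of the curves: fitted curves legitimately cut
staircase corners by a fraction of a voxel, and a mask only as wide as
the direction-carrying core would misclassify such pathways as leaving
the white matter. FA is 0.8 inside that tube and 0.05 outside, chosen to
sit clearly on either side of the default `FA_th` = 0.15 so stop-rule
tests are crisp; tube voxels without directions also mimic the
partial-volume rim of real bundles (high FA, no usable peak). Endpoint
ROIs are two-voxel-deep caps. `generate_odf()` builds
ODF samples as mixtures of the antipodally symmetric kernel
$\exp(\kappa((v\cdot\mu)^2-1))$ over the voxel's axes (default
$\kappa = 40$, a sharpness at which 64-direction sampling resolves
orthogonal crossings cleanly), with optional multiplicative Gaussian noise
clipped at zero; all randomness is fixed by the spec's seed.

What the phantom does **not** emulate: Rician acquisition noise, partial
Fourier and eddy-current artifacts, fanning/kissing geometries, partial
volume against gray matter, or curvature radii comparable to the voxel
size. Tests passing on these phantoms therefore demonstrate geometric
correctness of the pipeline, not robustness to acquisition physics.

Default problem sizes: 20³ voxels at 1 mm for single-bundle phantoms, and
52³ for the crossing phantom, which yields just over 100 bundle-voxel
seeds and, tracked in both NURBS modes, over 200 pathways for the
branch-switch count.

## Numerical choices

* Basis functions use the Cox–de Boor recursion with the right-continuous
  convention at interior knots and $u=1$ assigned to the last non-empty
  span (0/0 terms taken as 0); tests cross-check evaluation against an
  independent implementation of de Boor's pointwise algorithm.
* Duplicate-crossing unification replaces the earlier exact-coincidence
  merge (tolerance $10^{-6}$ mm) and subsumes it.
* Candidate ties in chain extraction are broken at $10^{-9}$ tolerance in
  the documented order (distance, angle, probability, voxel index) for
  bit-reproducible tracking; the whole pipeline is deterministic, so
  identical configurations produce byte-identical tractograms.
* Degenerate inputs: constant ODF profiles yield empty direction sets;
  all-coincident control points yield a two-point pathway with a warning;
  empty seed lists yield empty tractograms.

## Known limitations

* **Tangent quantization.** Control points are anchored to the voxel
  boxes and centers of a 26-connected chain, so a fitted curve's tangents
  inherit the staircase of the chain. Near flat runs of a circular bundle
  of radius $r$ on voxels of size $h$ the worst-case tangent error is
  about $\sqrt{2h/r}$ radians, and shrinking the voxels only improves the
  RMSE like $\sqrt{h}$. On the bundled arc phantom ($r=10$ mm, $h=1$ mm)
  the NURBS modes reach spatial RMSE well under half a millimeter while
  the tangent RMSE plateaus near ten degrees; the streamline baseline,
  which integrates the direction field directly at 0.02 mm steps, does
  not share this limit. The acceptance script reports both side by side.
* **Greedy, single-best propagation.** Chains never branch except at the
  seed; ambiguous crossings resolve by the documented ranking rather than
  by exploring alternatives.
* **Axis-aligned grids only.** NIfTI orientations restricted to scaling
  plus translation; oblique affines are rejected on read.
* The bidirectional half-budget rule truncates chains seeded far
  off-center on bundles longer than `L_th`/2 per side, which depresses
  valid-connection percentages on long phantoms even when tracking is
  geometrically perfect.
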
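---
title: "Shape-constrained graph-cut segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-constrained graph-cut segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

`shapecut` segments a single bright organ (the motivating case is the liver
in contrast-enhanced CT) from a 3D scalar volume, fully automatically, in
two stages.

**Coarse stage — multi-atlas initialization.** A set of reference subjects
("atlases": an intensity volume plus a binary organ label), *already warped
onto the target grid by an external registration tool*, is fused into an
initial mask. Each warped atlas is scored by normalized mutual information
against the target over a region around the candidate organ,

$$r_i = \frac{\mathrm{NMI}(I, A'_i;\Omega)}{\max_j \mathrm{NMI}(I, A'_j;\Omega)},$$

atlases with $r_i \ge \varphi$ (default $\varphi = 0.8$) are kept, and their
labels are combined by weighted majority voting with weights
$\omega_i = r_i$. Registration itself is out of scope: for real data we
recommend an affine + B-spline FFD pipeline (e.g. elastix) with
nearest-neighbour resampling of the labels.

**Fine stage — iterated shape-constrained graph cut.** From the current
shape $\Phi_0$ an unsigned Euclidean distance field is computed (anisotropic,
mm). Interior voxels deeper than $\Phi_s = 25$ mm become hard source seeds;
exterior voxels farther than $\Phi_t = 35$ mm are collapsed into the sink
terminal; the graph covers the band: the whole interior plus the exterior
shell closer than $\Phi_t$. On this band the energy

$$E(L) = \sum_p \big(\alpha D_p(L) + \beta J_p(L) + \gamma S_p(L)\big)
        + \sum_{\{p,q\}} B_{p,q}(L_p, L_q)$$

is minimized exactly by s–t min-cut ($\alpha = \beta = 10$, $\gamma = 80$,
5 iterations), the organ side is reduced to its largest 6-connected
component with sealed tunnels and filled cavities, and the result becomes
the next $\Phi_0$.

The terms:

* **Data** $D_p$: negative log-likelihood of the 2-channel feature vector
  (intensity, Gaussian-blurred intensity at $\sigma = 1$ voxel) under a
  Gaussian fitted to the corresponding seed region.
* **Appearance** $J_p$: per orthogonal plane (XY, XZ, YZ), 2D LBP codes
  ($P = 8$, in-plane radius $R = 1$, z radius $L = 2$ for the XZ/YZ planes)
  are pooled over a local window into a cumulative histogram, compared by
  the L1 Wasserstein distance to a seed-region reference $H_0^i$ and scaled
  by $(\sigma_0^i)^2$.
* **Shape** $S_p = 1 - \exp(-d(p, \Phi_0)/r_0)$ with $d \equiv 0$ inside,
  $r_0$ the enclosing-sphere radius: growing far beyond the current shape
  is progressively penalized, shrinking is never shape-penalized.
* **Boundary** $B_{p,q} = \exp(-\omega_{pq}\,\lVert x_p - x_q\rVert^2 /
  2\sigma_1^2) / \mathrm{dist}(p,q)$ with $\omega_{pq}$ the Earth Mover's
  Distance (L1 ground metric, normalized to $[0,1]$) between 4×4
  spin-image-like descriptors of the two voxels
  ($\sigma_d = \sigma_i = 0.5$, patch radius 4 voxels): a *texture* edge
  makes the feature difference count more, so cuts gravitate to texture
  interfaces even where intensity is flat.

The intensity-only baseline (`segment_intensity_only`) is the classical
formulation: $\lambda \cdot$ 1D-intensity NLL regional term ($\lambda=10$),
$\omega \equiv 1$ boundary term, same automatic seeds, one cut, no shape or
appearance terms.

# Interpretive decisions in the energy

**Which t-link gets which term.** In an s–t graph the edge (source, p) is
cut when p ends background, so it carries the background-label cost, and
(p, sink) the organ-label cost. The printed energy does not say which label
each of $D, J, S$ argues against. We charge:

* organ label: $\alpha D_p^{fg} + \beta J_p^{fg} + \gamma S_p$,
* background label: $\alpha D_p^{bg} + \beta J_p^{bg}$.

**$J_p(L)$ as a per-label appearance cost.** $J$ as printed depends on a
label argument. We read it as: each label pays the Wasserstein dissimilarity
of the voxel's windowed LBP histograms to *that label's* seed-region texture
reference — source seeds for the organ, the exterior shell just beyond
$\Phi_t$ for the background — each scaled by its own
$(\sigma_0^i)^2 = \max(\mathrm{mean}_q\, WD(H_q^i, H_0^i)^2, 10^{-6})$
estimated on its region. Because LBP codes are invariant to monotone
intensity shifts, a smooth structure at *identical intensity* to the organ
still resembles the background's texture class, which is precisely the
discrimination the equal-intensity failure mode needs. A single-reference
variant (all of $J$ charged to the organ label) is kept for API completeness
but is not the pipeline default: with only one reference the term cannot
distinguish "window straddles the organ boundary" from "window inside a
foreign structure", and acts as a pure erosion force.

**Non-negative capacities.** Gaussian log-densities can be positive
(continuous NLL below zero); both t-links of a voxel are then shifted up by
the same amount, which changes no labeling comparison.

**Solver.** The default max-flow is a Boykov–Kolmogorov implementation
(`src/maxflow.cpp`), the standard choice for vision grid graphs; igraph's
max-flow is retained as an independent exact route (`min_cut(g, "igraph")`)
and the test suite cross-checks both against exhaustive enumeration.

**Shape update.** The cut's organ side is reduced to its largest
6-connected component, morphologically closed with radius 1, and enclosed
cavities are filled. The closing is deliberate: dark parenchyma clusters
occasionally get carved with a voxel-wide channel to the exterior, turning
what should be a fillable cavity into a tunnel; sealing such tunnels is
required for "$\Phi_0$ is a single closed surface" to hold, which the next
distance field assumes. It is applied after component selection so that
discarded structures can never be re-attached.

**Model re-estimation.** Gaussian models and LBP references are re-fitted
from the updated seed regions at every iteration (default). With a
realistically imperfect initialization the first estimates are contaminated
and must adapt as the shape improves. `refit_each_iteration = FALSE`
freezes the first estimates; it is slightly more stable when the
initialization is already near-perfect, and available for that regime.

# Units and scales

* $\Phi_s, \Phi_t$ are interpreted in **mm** (spacing-invariant); a
  `threshold_units = "voxels"` switch exists because the source values are
  bare numbers.
* Intensities are min-max normalized to $[0,1]$ internally before feature
  extraction; $\sigma_1 = 0.1$ is calibrated on that scale.
* The LBP pooling window default, 15×15×7 **voxels**, matches clinical CT
  grids (~0.7×0.7×2 mm, i.e. ~10.5×10.5×14 mm physical). On much coarser
  grids the same voxel count would pool a 3× larger physical region and the
  appearance term loses its locality; `window_mm = c(10.5, 10.5, 14)`
  requests the physical extent instead, and the phantom experiments use it.
* LBP radii ($R$, $L$), the blur $\sigma$, and the spin patch radius stay in
  voxel units: they are voxel-neighborhood operators by construction.
* $(\sigma_0^i)^2$ floor $10^{-6}$; covariance regularization
  $\xi \mathrel{+}= \max(10^{-6}\,\mathrm{tr}(\xi)/d,\,10^{-8}) I$; both
  exist for the constant-intensity regions that phantoms produce.
* Spin descriptors bin the patch distance mapped to $[0,4)$ and the
  *per-patch* min-max normalized intensity mapped to $[0,4)$ (bin centers at
  0.5, …, 3.5); a constant patch pins the intensity coordinate to bin 0's
  center. Per-patch normalization keeps the descriptor contrast-local and
  preserves exact rotation invariance.

# The synthetic world

`phantom_spec()` / `standard_suite()` generate targets with ground truth
and pre-warped atlas pairs. What the defaults emulate, and why:

* **Intensity world**: background soft tissue ≈ 60, organ parenchyma ≈ 105
  (arbitrary units), additive noise sd 8 — contrast-to-noise ≈ 5, as in
  enhanced abdominal CT. A 20σ-separable toy contrast would make every term
  other than the data term irrelevant and validate nothing.
* **Correlated speckle** (8% multiplicative, correlation length ~1.2
  voxels) inside the organ. Uncorrelated salt/pepper is *statistically
  invisible to LBP*: the sign of a neighbor difference under i.i.d.
  symmetric perturbations is a fair coin exactly like additive noise. Only
  spatially correlated texture produces coherent sign patterns.
* **Bias field** (smooth, sd 6) and **clutter blobs** at organ-like
  intensity in the far background: a constant background would give the
  fitted background model a degenerate covariance (real CT backgrounds are
  heterogeneous and contain bright organs), which distorts both t-links.
* **Atlas jitter**: smooth random displacement fields, with 80% of the
  variance *shared* between atlases — registration error has a systematic
  component that label voting cannot cancel. The shared field's worst-case
  displacement is pinned at 28 mm so that the fused initialization matches
  the reported multi-atlas initialization quality on real CT (ASD ≈ 4 mm,
  MSD ≈ 23–41 mm) while staying inside the recoverable band
  ($\Phi_t$ = 35 mm): initialization error beyond $\Phi_t$ is outside the
  graph by construction and no refinement could ever reach it.
* The four suite cases mirror the canonical difficulty modes: (1) adjacent
  equal-intensity structure separated only by texture, (2) internal
  low-attenuation lesions (labelled as organ; recovered by cavity filling),
  (3) a thin protrusion next to an equal-intensity tube, (4) a flat
  interface against a large equal-intensity mass.

What a green phantom test does **not** establish: anatomical realism
(ellipsoids are not livers), registration behaviour (atlas warps are
synthetic), scanner physics (no beam hardening, partial-volume is only the
implicit voxelization), or performance at clinical resolution (the phantoms
are 2–3 mm isotropic; the reference resolution is ~0.7 mm in-plane, where
the same one-voxel boundary bias costs three times less surface error).

# Numerical choices

* Distance fields: exact anisotropic squared-EDT (Felzenszwalb–Huttenlocher
  three-pass), surface = foreground voxels with a background 6-neighbor.
* 1D Wasserstein = L1 between cumulative histograms; EMD on the 4×4 bin
  grid = min-cost flow on the 4-neighbor grid graph (an L1 ground metric is
  a geodesic metric on that graph), solved exactly by successive shortest
  paths; both are cross-checked against an explicit LP oracle.
* Ties in LBP thresholding: $s(0) = 1$; bilinear sample coordinates are
  snapped within $10^{-9}$ of grid points so constant volumes yield exact
  code $2^P - 1$.
* Vote ties break toward the smaller class index (background wins), making
  fusion deterministic and conservative.
* Infinite capacities are $10^6 \times$ the largest finite capacity.
* Empty hard-seed fallback: the deepest-core voxels (within one voxel
  diagonal of the interior distance maximum). A single-voxel anchor is not
  used because a min cut can collapse around it.
* The refinement stops early only at an exact fixed point (identical mask),
  which cannot change the result.
* Everything is deterministic given inputs; randomness exists only in the
  phantom generator, which takes an explicit seed.

# Known limitations

* A ~1-voxel boundary bias is intrinsic at coarse grids: boundary voxels
  are partial-volume mixtures that fit neither region model.
* Dark internal structures whose exclusion channel is wider than the
  closing radius can still be carved (the documented low-attenuation
  failure mode of intensity-driven cuts).
* The shape term penalizes outward growth only; it does not oppose
  shrinkage. Robustness to shrinkage comes from the data term and model
  re-estimation.
* The NMI region policy, histogram bin count (32), and background shell
  (10 mm beyond $\Phi_t$) are pragmatic defaults; none have a source-stated
  value.
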
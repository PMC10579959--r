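---
title: "Aligning left-atrial imaging and mapping anatomies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning left-atrial imaging and mapping anatomies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrialign)
```

This vignette documents the registration model implemented by `atrialign`,
the choices made where the problem leaves the design open, the synthetic
phantom the package validates against, and the limits of what that
validation shows.

## The registration model

Two surface anatomies of the same left atrium are available in unrelated
coordinate frames: a labeled segmentation from CT or MRI (the *moving*
surface) and an electro-anatomical mapping (EAM) anatomy (the *fixed*
surface, usually unlabeled). Only a rigid transform — rotation `R` and
translation `t`, in millimetres — relates them; scaling or deformation is
deliberately out of scope, because a deformable fit could silently absorb
real anatomical or physiological differences between the acquisitions.

Both clouds are treated as samples of locally planar patches rather than as
distinct landmarks. Given correspondences `(p_i, q_i)` — each moving point
paired with its nearest fixed point — and unit normals `n_i` of the fixed
surface at `q_i`, one iteration of the registration minimizes the
point-to-plane cost

$$ C(R, t) = \sum_i \big[ (R\,p_i + t - q_i) \cdot n_i \big]^2 . $$

Sliding along the local surface is free; only out-of-plane residuals are
penalized. On smooth chamber walls this converges far faster than the
point-to-point variant and is insensitive to how the two acquisitions happen
to sample the same wall.

### Solving one iteration

`solve_point_to_plane()` linearizes the rotation for small angles,
`R ≈ I + [ω]×`, turning the cost into a linear least-squares problem in
`(ω, t)` with the familiar 6×6 normal system (rows `[p × n; n]`). Two
details matter:

* **The linear step is iterated** (Gauss–Newton) on the *fixed*
  correspondences until the cost stops improving, re-projecting the rotation
  onto SO(3) by polar decomposition after every step. A single linearized
  solve leaves an `O(θ²)` cost gap that is irrelevant inside an ICP loop but
  means the solver would not actually attain the minimum of its own cost;
  iterating closes that gap to numerical precision (the test suite verifies
  agreement with a generic 6-parameter numeric minimizer to 1e-6 mm²).
* **Rank-deficient systems take the minimum-norm solution** (pseudo-inverse)
  by default. The canonical degenerate case — all normals parallel, e.g. a
  planar patch — still has a well-defined answer for the *constrained*
  degrees of freedom (translation along the normal, the two tilts), and the
  minimum-norm solution returns exactly that with zero motion in the
  unconstrained directions. `strict_rank = TRUE` turns deficiency into an
  error for callers that need to detect unconstrained geometry.

### The ICP loop

`icp_point_to_plane()` repeats: transform the moving cloud, match each
moving point to its nearest fixed point (an exact grid-hash search), discard
pairs farther than `rejection_distance_factor` (default 3) times the median
pair distance, solve, compose. Inside the loop the solver takes a *single*
linearized step per iteration: fully minimizing on the current — partly
wrong — correspondences overshoots and destabilizes the descent, whereas
one conservative step per re-matching is the classic, stable recipe.
Iteration stops when the relative change in point-to-plane RMSE falls below
`rmse_rel_tolerance` (default 1e-4), when the RMSE is essentially zero, or
after `max_iterations` (default 50). The tracked RMSE is evaluated over
*all* moving points (not just the surviving pairs), so successive iterations
are compared on the same footing; with membership-churning subsets, genuine
progress can otherwise masquerade as an RMSE raise.

The accepted RMSE sequence is kept non-increasing: an iteration that raises
the RMSE is discarded and terminates the loop. Because correspondences are
re-matched every iteration, such a raise almost always means the iteration
is oscillating at its cost floor, so it is classified as convergence
(stagnation). `converged = FALSE` is reserved for the one genuinely
different situation — the iteration cap was reached while the RMSE was still
improving. An alignment stuck in a *wrong basin* typically stagnates too;
catching that is the job of the residual-distance flag, not of the
convergence classifier.

**Initialization.** The anatomies' frames are unrelated in general. The
default start is centroid alignment (pure translation), which carries the
method through combined perturbations of roughly 20–35° and 10 mm on
phantoms. `centroid_pca` aligns the principal axes as well, trying the four
proper sign assignments and keeping the lowest initial RMSE; it extends the
capture range to arbitrary translations and large rotations, at the cost of
being fooled by near-symmetric shapes. `identity` is available when the
frames are known to agree.

## The two-stage pipeline

`align_la()` composes the clinical procedure:

1. **Resampling trigger.** Segmentation exports are frequently
   *non-isotropic*: some regions carry far more points than others, which
   biases every distance-driven step toward the oversampled regions. Any
   input failing an isotropy check is resampled (next section). EAM
   anatomies and already-uniform meshes pass through untouched.
2. **Stage 1 — full anatomies.** The pulmonary veins, appendage and mitral
   annulus are the most distinctive landmarks; including them anchors the
   global pose.
3. **Stage 2 — structure exclusion.** Those same structures are segmented
   differently by different modalities (vein stubs truncated at different
   lengths, appendage depth, annulus delineation), so after the pose is
   found they are removed (default exclusion set: all four PVs, LAA, mitral
   annulus; configurable to the PV+annulus subset) and the registration is
   re-run on copies of the surfaces, initialized at the stage-1 result and
   capped at **3 iterations** so it refines rather than re-solves. The
   returned `composed_transform` is `stage2 ∘ stage1`.
4. **Metrics and flag** (below).

### Does stage 2 help? An honest account

On phantom pairs whose PV/appendage tube lengths disagree — the obvious way
to mimic segmentation discrepancy — the package's own acceptance experiment
(`exclusion_benefit_median_mm` in `scripts/acceptance.R`) finds the
body-only median residual of the two-stage fit *indistinguishable from* the
single-stage full-anatomy fit: the measured benefit hovers around ±0.001 mm
on a ~0.77 mm discretization floor, with per-pair wins near 50%. The reason
is that two robustness mechanisms already neutralize tube-length mismatch in
stage 1: the median-factor correspondence rejection discards overhanging
tube points once the alignment is close, and the point-to-plane residual
against an open tube's radial normals is insensitive to axial overhang. The
refinement stage is therefore kept for its clinical rationale — protection
against structure discrepancies that *do* project onto surface normals
(shape, angulation, annulus delineation) — while the package reports the
tube-length experiment as it measures it, not as one might wish it to come
out. The companion guarantee that stage 2 never *hurts* (its median residual
never exceeds stage 1's by more than 1e-6 mm on capture-range phantoms) is
enforced by the acceptance suite.

### The automatic pass/fail flag

A visual plausibility check by an observer does not automate directly;
`flag_alignment()` replaces it with three mechanical criteria, tested in
order: median residual ≤ `fail_median_mm` (default 5 mm, the outer quality
threshold of the metrics); stage 1 converged; stage-2 final RMSE at most 20%
above stage 1's. **Known limitation:** a chamber body is close to an
ellipsoid, and an alignment that falls into a symmetry-related wrong basin
can exhibit a small body-only median residual and pass all three checks even
though the excluded structures are grossly misplaced. A check on the
excluded structures themselves would be circular (they are excluded because
they disagree between modalities); reviewing flagged-pass alignments
visually remains good practice, exactly as with manual workflows.

## Isotropic resampling

`isotropic_remesh()` measures isotropy as the coefficient of variation (CV)
of the spacing distribution — edge lengths for meshes, nearest-neighbour
distances for point clouds. Surfaces already below the CV threshold
(default 0.3) at roughly the target spacing are returned unchanged, which
makes the operation idempotent and doubles as the pipeline's remeshing
trigger.

Resampling draws candidates uniformly on the triangulated surface
(area-weighted, so every output point lies exactly on the input surface —
the `max_surface_deviation` budget, default 0.5 mm, is consumed only by the
input mesh's own chordal error) and thins them by greedy Poisson-disk
rejection at radius `target_spacing`. Labels transfer from the nearest
corner of the candidate's triangle. Point clouds without faces are thinned
directly. The draw is seeded and fully deterministic. Achieved spacing CV on
an analytic sphere is ~0.1–0.2, comfortably below the threshold, with point
density `area / (c · spacing²)`, `c ≈ 1.4–1.9`.

The default `target_spacing` of 1.5 mm sits between the MRI voxel pitch
(0.625 mm) and typical EAM inter-point distances; dense CT meshes (often
>100k vertices) are downsampled by the same trigger, which extends the
original MRI-only remeshing practice to any oversampled input (a
`remesh_mode` flag restores imaging-only or no remeshing).

## Residual-distance metrics

`residual_distances()` removes the excluded structures from the imaging
side, then measures each retained vertex's Euclidean distance to the EAM
anatomy, reporting the median, mean and percentage of the retained surface
below 2.5 mm and 5 mm. Defaults and the reasoning where the convention is
open:

* **Direction**: imaging → EAM, because the exclusion labels live on the
  imaging side; a `symmetric` mode pools both directions.
* **Target**: nearest EAM *vertex* by default — with both clouds
  isotropically sampled the difference to a true point-to-surface distance
  is bounded by the spacing — and nearest point on the EAM *triangulation*
  (`mode = "surface"`) when faces exist.
* The cohort statistic "average median" is the unweighted mean of per-case
  medians.

`distance_map_export()` writes the per-vertex map as a PLY scalar property
(excluded vertices carry a sentinel) for regional inspection in any mesh
viewer.

## The synthetic phantom and its noise model

`generate_phantom()` builds a labeled LA look-alike: an ellipsoidal body
(default semi-axes 30 × 25 × 22 mm, a ~45 ml adult-sized chamber), four
cylindrical PV stubs on the posterior wall (radius 5 mm, length 10 mm), one
tapering appendage lobe, and a mitral rim band around an inferior opening,
all Poisson-disk sampled at the target spacing. Candidates are drawn and
thinned per structure in a fixed order, so changing one tube's length leaves
the sampling of the body and the other structures bit-identical — the
property the mismatched-pair experiments rely on. `simulate_acquisition()`
produces the EAM counterpart: a ground-truth rigid displacement, isotropic
Gaussian point noise (default SD 0.5 mm, a realistic mapping-catheter
localization error), optional spacing jitter, contiguous-patch dropout
(unmapped regions are spatially coherent, not i.i.d.), and label stripping.

What the phantom does **not** emulate: true vein/appendage curvature and
branching, wall motion and volume change between acquisitions, systematic
shape differences between segmentation pipelines, and EAM surface
reconstruction artefacts (fused ostia, interpolated patches). Passing tests
on phantoms therefore demonstrates that the *algorithm* recovers known rigid
displacements under noise and partial coverage — not that any particular
clinical accuracy will be achieved on patient data.

**Noise-model oracle.** Under a perfect alignment, the residual distance at
an imaging vertex is the minimum over nearby EAM points of a
Gaussian-displaced distance. `mc_noise_residual()` simulates exactly that on
the actual phantom geometry (each draw displaces a vertex and its 30 nearest
neighbours and records the minimum distance), giving an independent
prediction of the cohort median that the full pipeline must reproduce within
15% — a check that alignment under noise is unbiased, not merely convergent.

## Problem sizes, determinism, numerics

The validation cohorts use phantoms at 2–2.5 mm spacing (~900–1500 points)
for the recovery, noise and determinism experiments and the default 1.5 mm
(~2400–4600 points) where the discretization floor matters
(exclusion-benefit pairs); the Monte-Carlo oracle uses 1e5 draws. These
sizes make every experiment reproducible in seconds while leaving all
spacing-dependent effects resolvable.

All randomness flows from explicit integer seeds through one generator per
call (`.Random.seed` is saved and restored, so library calls never perturb a
session's RNG stream); identical inputs and seeds reproduce phantoms,
cohort tables and fits bit-identically, and every cohort run records a
provenance block (config fingerprint, master seed, package and R versions).
Numerical guard-rails: rotations are validated orthonormal to 1e-9 and
re-projected by polar decomposition after every linearized step; the
accepted RMSE sequence is monotone to 1e-9; rank decisions in the 6×6 solve
use a 1e-10 relative singular-value cutoff; nearest-neighbour searches are
exact (grid hash with ring-expansion proof), not approximate.

## Known limitations

* Offline use only: the pipeline consumes exported anatomies; it has no live
  link to a mapping system.
* Rigid transforms only, by design.
* The automatic flag can pass symmetry-related wrong basins (see above).
* `centroid` initialization assumes the frames are not arbitrarily rotated;
  use `centroid_pca` otherwise.
* Vendor-proprietary EAM export archives are not parsed; surfaces must
  arrive as PLY/OBJ/STL/xyzl.
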
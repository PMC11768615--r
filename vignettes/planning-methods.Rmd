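---
title: "Volumetric milling-area planning: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric milling-area planning: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model of the milling problem, the parameters that matter and their
defaults, what the synthetic phantom does and does not emulate, the
numerical choices, and the known limitations.

## The planning problem

Mastoidectomy opens a surgical channel through the temporal bone to a deep
target (here modeled after an acoustic neuroma). The channel
`C_channel = C_ex ∪ C_in ∪ C_mill` is the union of the external space, the
internal cavities reachable from it, and the milled bone. Critical
structures split into two roles: those that must remain intact (`H`: sinus
dura, facial nerve, ossicles, carotid), each carrying a minimum safe
distance `d_risk`, and those whose damage is penalized but tolerated
(`S`: scala vestibuli), each carrying an injury weight `λ`. The plan must
guarantee `C_mill ∩ C_h = ∅` structurally while trading off three
objectives: constructability `Q_c`, target accessibility `Q_a = −μ_a`,
and injury `Q_i`.

## Stage 1: the maximum milling area

The tool is a cylinder of radius `r` (default 1.5 mm, configurable; it is
the single tool dimension used everywhere — cylinder radius, contour
downsampling interval, closing kernel). A straight trajectory from entry
`k` to target point `t` is feasible iff for every intact structure `i`

```
min-distance(structure_i, segment(k, t)) > r + d_risk_i
```

with clinical safe-distance defaults of 0.5 mm for scala/ossicle/carotid-
class structures, 1.5 mm for the sinus-dura class, and 2.5 mm for the
facial-nerve class (overridable per structure in the run configuration).
The union of all feasible open cylinders, grouped per target point
(`C_mill⁰(t)`, entries `K(t)`), is the maximum milling area `C_mill⁰`.
Because only feasibility-checked cylinders are ever instantiated, *every*
downstream plan — any parameter vector — inherits the safety margin; this
is audited in the tests by SDF lookups at milled voxels.

Distance queries use per-structure signed distance fields (SDFs) computed
once by an exact separable Euclidean distance transform. The sign
convention is negative inside; the magnitude uses the half-voxel boundary
convention (`d − spacing/2`), which provably tracks the
nearest-surface-voxel distance within half a voxel and keeps penetration
detectable as a sign flip. Segment queries interpolate the SDF
trilinearly at samples spaced half a voxel apart: the sampling error is
then bounded below the voxelization error already present. A
nearest-voxel lookup mode exists as well; interpolation is the default
because it recovers up to half a voxel of accuracy at no real cost.

Entry candidates are the approach-facing outer-surface bone voxels whose
projection onto the plane orthogonal to the approach axis falls within a
disk (default radius 12 mm) around the target centroid. How the entry set
is seeded on the skull is a convention, so it is isolated behind one
operation (`find_entry_candidates()`) and can be replaced.

Per target, entries are traversed in a deterministic near-to-far sweep
starting from the entry closest to the approach line, so that the
early-termination rule is meaningful and reproducible: traversal stops
once the relative volume gain

```
G_t(k) = ΔV · voxel_volume / (|kt| · π r²)
```

stays below 5×10⁻⁴ for 25 consecutive entries (the window size
operationalizes "consistently below"; the threshold is part of the
method). On the default phantom the early-terminated volume differs from
exhaustive traversal by well under 2%.

## Stage 2: the effective target boundary

Optimizing every target surface voxel would be hopeless, and only the
surface facing the approach needs exposure. The reduction is:

1. **T1 — orientation.** For each surface voxel `t` with outward normal
   `n_t` (estimated as the gradient of the target SDF after separable
   1-2-1 smoothing — the smoothing suppresses the voxel staircase and
   keeps sphere-normal errors below ~10° at 1 mm voxels), count the
   entries `k` with `θ(t,k) = arccos(n_t · tk) < π/2`; keep `t` iff its
   count strictly exceeds the mean and 5% of `|K|`. Ties are broken by
   exclusion (the strict inequality as specified).
2. **T2 — accessibility.** Entries subsampled on a `2r` world grid (one
   deterministic representative per cell); keep `t` iff any subsampled
   entry is feasible, stopping at the first success.
3. **T3 — contour.** Boundary points of the accessible patch, ordered
   clockwise by polar angle of their control-plane projection about the
   projected centroid. Clockwise is defined looking along the plane
   normal (+approach); the handedness is a convention, fixed and tested.
   If the patch fragments (possible on voxelized caps), the largest
   26-connected component is used with a warning — targets are assumed
   convex.
4. **T4 — downsampling.** Greedy arc-length walk emitting a point every
   `r` millimetres, guaranteeing partial overlap of adjacent access
   trajectories. On the default phantom this leaves 18 points (the
   expected order of magnitude is a few dozen), hence `18 × 8 = 144`
   optimization parameters.

## Stage 3: parameterization on the control plane

Each target's feasible entries project along the rays `t→k` onto a control
plane parallel to the A–S plane. The plane sits at the entry surface
(median entry R level), with its origin at the projected target centroid
and a pixel pitch equal to the planning voxel spacing; placing it at the
entry surface makes the projection nearly the identity on the entries,
which keeps the all-ones reconstruction essentially identical to the
maximum area (Dice 1.0 on the phantom). Each raster cell remembers its
originating entry (nearest-to-plane wins ties); the raster is closed with
a disk of radius `r` — discretized by pixel coverage, so the closing can
bridge sub-kernel gaps despite digitization — and closing-added cells
inherit the nearest mapped cell's entry.

The per-target area is deformed in polar coordinates about its mass
center by a periodic cubic spline `σ_t(θ) ∈ (0, 1]` through `N = 8`
uniformly spaced control points: a cell at `(ρ, θ)` survives iff the cell
at `(ρ/σ_t(θ), θ)` is occupied *and* the cell itself is occupied (the
subset restriction, which makes deformation contractive regardless of the
area's shape). Numerical choices: the source cell is found by direct
nearest-cell lookup on the native raster at the exact angle (no
intermediate angular binning); σ is clipped into `[10⁻³, 1]` so the open
interval `(0, 1]` is honored without division blow-up; and the mass
center is frozen from the undeformed area so the parameter-to-shape map
is stationary across optimization iterations. The milling volume of a
parameter matrix is the union of the cylinders of all surviving cells'
entries, clipped to bone.

## Stage 4: objectives

**Accessibility.** `μ_a` is the mean over effective targets of the
fraction of deterministic Fibonacci-spiral hemisphere directions
(approach side; default 64, seeded phase) whose radius-`r` capsule ray
from the target to the grid boundary stays inside the channel, tested
against the channel's inner distance field with a one-voxel ε-ball
exemption at the target. The underlying accessibility notion comes from
prior work on channel evaluation and is deliberately isolated behind one
operation; on a voxelized cone channel the measured fraction matches the
analytic solid angle within 0.05.

**Injury.** `Q_i = λ_bone V(C_mill)/V(C_bone) + Σ_j λ_j V(C_mill ∩
S_j)/V(S_j)` with weights validated to sum to one; by default
`λ_bone = 0.5` and the remainder splits equally across S structures.

**Constructability.** `Q_c = −(μ_gsc/μ_gsc⁰)·e^{μ_sa}`. The global
spatial compactness `μ_gsc` is the ordered-pair sum of inverse distances
between mutually visible voxels of the milling volume (obstructed pairs
contribute zero; line of sight is tested at half-voxel steps). The full
double sum is quadratic in volume, so a seeded 200-voxel subsample
estimates it, scaled by `n(n−1)`; the exhaustive sum is retained as an
oracle mode and the estimator stays within 5% of it on small shapes. It
is computed on the milling volume (not the whole channel) by default,
switchable. The smoothness `μ_sa` is the spectral arc length of the
boundary of the union of deformed areas on the control plane: the
contour is resampled to 512 uniform arc-length points, the complex unit
tangent is Fourier-transformed, and the arc length of the max-normalized
magnitude spectrum up to `ω_c = 20` cycles per circuit is negated.
Because the tangent of a closed contour is periodic, the package uses
the exact harmonic spectrum (FFT length = resampling count) rather than
zero-padding: padding a periodic signal only convolves the line spectrum
with a Dirichlet kernel whose sidelobe ripple swamps the shape
differences the metric exists to measure. The two-sided spectrum is
folded onto positive frequencies so the traversal orientation of the
contour (clockwise vs counterclockwise) cannot flip the result. Both
choices are exposed in the configuration.

## Optimization

The `N_T × 8` parameter matrix, bounded to `(10⁻³, 1]`, is optimized by
NSGA-III with Das–Dennis reference directions. The initial population
always contains the all-ones individual (the maximum milling area), so
the baseline plan is never lost. Defaults: population 92 with 12
partitions (91 reference directions) and 100 generations for full runs;
the bundled phantom studies use population 40, 7 partitions (36
directions), 30 generations, which converges in under a minute at 1 mm
resolution. SBX crossover (η = 15, p = 0.9) and polynomial mutation
(η = 20, p = 1/n) are conventional settings, all in the configuration.
A vanished plan (every area deformed to empty) is penalized with
objectives `(10⁶, 10⁶, 10⁶)` instead of raising, because evolutionary
loops need total functions. Metric seeds are fixed per problem, so the
objective function is deterministic in the parameters and identical
seeds reproduce identical fronts; the compactness sampler saves and
restores the global RNG state so metric evaluation cannot perturb the
optimizer's random stream.

From the front, two candidates are picked — compromise programming
(minimum Euclidean distance to the ideal point on min–max-normalized
objectives) and the equal-weight pseudo-weight rule — and the final plan
is whichever has the larger compactness of its reconstructed volume. The
L2 norm and the equal weights are choices; the selection provenance is
recorded in the result.

## The synthetic phantom

The phantom emulates the *constraint topology* of a temporal-bone scene
with closed-form shapes on a 60 mm cube (1 mm voxels by default): a
lateral bone slab of sinusoidally varying thickness, a deep ellipsoidal
target (semi-axes 6 × 6.5 × 6.5 mm, a mid-sized neuroma), a
facial-nerve-like tube (radius 1.5 mm, d_risk 2.5) and an ossicle-like
capsule flanking the corridor, a sinus-dura-like sheet (3 mm thick,
d_risk 1.5), and a scala-like tube (radius 2 mm, λ = 0.5) embedded in
the bone slab at the edge of the feasible bundle so that the maximum
milling area clips 5–20% of its volume — giving the optimizer a real
injury gradient, which is asserted in the tests. A guaranteed-clear
corridor capsule is validated analytically at build time, so every
generated scene admits at least one feasible trajectory. The seed only
perturbs the bone-thickness modulation phase; all shape parameters stay
closed-form so tests can build exact distance oracles (segment-segment
for capsules, convex 1-D minimization of the point-box distance for
sheets, dense surface sampling for ellipsoids).

What the phantom does *not* emulate: CT intensities and artifacts,
segmentation error, anatomical shape variation, non-convex or multiple
targets, and the paper-scale 0.25 mm planning resolution (the package
supports it — `planning_spacing_mm` — but the bundled studies run at
0.5–1 mm so the full pipeline stays interactive). Passing tests
therefore demonstrate the correctness of the geometry, metrics, and
optimization machinery under known ground truth — not clinical
performance on real anatomy.

## Degenerate inputs and edge behavior

Empty or full masks have no surface and are rejected by the SDF; segment
queries outside the grid raise (grids are padded by at least
`r + max d_risk` before planning); targets with no feasible entry are
dropped with a warning, and only an all-infeasible scene aborts; an
all-parallel entry projection or a fully vanished deformation is an
error at the API surface and a penalty inside the optimizer; fronts of
size one short-circuit selection with a recorded "degenerate front"
provenance.

## Known limitations

The tool is a cylinder — burr shapes or curved trajectories are out of
scope. The accessibility operationalization is a documented stand-in for
the external reference the formula descends from. Structure motion and
deformable anatomy are ignored. The compactness estimator is stochastic
(seeded); exhaustive mode exists but is quadratic. Clinical validation
requires real CT segmentations, which the package consumes (NIfTI masks
plus a YAML manifest) but does not provide.
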
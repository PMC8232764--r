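---
title: "Methods: non-rigid plant reconstruction and sensor fusion in plantfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-rigid plant reconstruction and sensor fusion in plantfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plantfuse turns a short sequence of depth frames of a moving plant into one
fused triangle-mesh model, then paints height-indexed environmental sensor
readings onto that model as color gradients. This vignette explains the
models and procedures behind each stage, the parameters that matter, what
the synthetic test bed does and does not establish, and the design choices
made where the design was genuinely open.

## The problem

A depth camera standing in a crop row records a plant for a couple of
seconds. The plant moves (wind), so consecutive frames see slightly
different poses, and each frame sees only the camera-facing side. Rigid
fusion would smear the moving leaves into multiple ghost copies; the goal
of non-rigid fusion is to deform the accumulated model into each new
frame's pose before merging, so data accumulates over time — thin leaves
thicken, occluded parts appear — without duplicated geometry. The output
feeds phenotyping: plant height, leaf width, stem–leaf angles are read off
the final mesh.

## Per-frame processing chain

Each selected frame passes through:

1. **Back-projection.** Every strictly positive depth sample is lifted by
   the pinhole model; zero depth means "no return" and is dropped. A full
   640×480 frame yields 307,200 points, most of them background.

2. **Logarithmic background removal.** A cutoff factor $f_{bg} \in [0,1]$
   is mapped through $x_b = b^{f_{bg}}$ (so the factor range spans
   $[\log_b 1, \log_b b] = [0,1]$) and then linearly onto the cloud's depth
   range:
   $$d_{bg} = -\frac{b - b^{f_{bg}}}{b - 1}\,\Delta d + d_{max},
   \qquad \Delta d = d_{max} - d_{min}.$$
   Because $(b^f - 1)/(b - 1) \le f$ for $b > 1$, the threshold always sits
   nearer the camera than the linear baseline
   $d_{min} + f_{bg}\,\Delta d$ — the right bias when the subject is the
   closest object. Larger bases cut closer. Depth here is the z coordinate
   (a pass-through filter), and $d_{min}, d_{max}$ are recomputed per frame
   so the cut adapts to each frame's depth range. Defaults: $b = 10$,
   $f_{bg} = 0.2$ (on a 0.29–22.9 m scene these give a 1.76 m cut; base 100
   gives 0.64 m).

3. **Octree standardization.** Points are pooled into voxels of a fixed
   resolution (default 3 mm at full sensor resolution; the bundled tests
   run 4–5 mm) anchored at the cloud's minimum corner. Four consolidation
   modes exist (centroid of points — the default, voxel centre, first or
   last inserted point, insertion order = input order).

4. **Outlier removal.** With $d_m$ the global mean of each point's mean
   distance to its $N$ nearest neighbors, a point whose local mean
   neighbor distance exceeds $f_{out}\, d_m$ is removed
   (defaults $N = 6$, $f_{out} = 2$). The pass is single-shot: all
   quantities are computed on the input cloud, so the result is
   independent of point order; re-running is the caller's choice.

5. **Bilateral smoothing.** Normals are estimated by PCA (smallest
   eigenvector of the k-neighborhood covariance, oriented toward the
   camera), then smoothed by angle-weighted averaging with weight
   $\exp(-(\theta/\sigma_\theta)^2)$ — the weight vanishes across sharp
   angle gaps, which is what preserves leaf edges. Points are then
   repositioned by a locally-optimal-projection-style update: each point
   moves **along its smoothed normal** onto the bilaterally weighted local
   plane of its neighbors (spatial Gaussian × normal-angle Gaussian
   weights within the support radius). Constraining the displacement to
   the normal direction leaves tangential spacing untouched; the
   tangential repulsion term of general-purpose LOP degenerates under this
   constraint and is absorbed into it. An exact plane is a fixed point;
   on noisy planes the RMS residual decreases monotonically per iteration.

6. **Advancing-front reconstruction.** The cloud is triangulated by greedy
   front growth: the seed is the candidate triangle with the smallest
   circumradius; a priority queue of candidates adjacent to the open front
   is drained smallest-circumradius-first. A candidate is rejected when it
   would create an edge shared by more than two triangles, reuse a
   directed edge (breaking orientability), fold back onto its neighbor
   beyond a dihedral guard, or attach to an already-used apex without
   sharing an existing edge (the fan-extension rule — without it,
   irregularly sampled scans degenerate into edge-manifold but
   vertex-overlapping triangle soup). On front exhaustion with unused
   points left, the algorithm reseeds among them; residual boundary cycles
   of at most `max_hole_edges` (default 8) close by ear filling. No new
   vertices are created. Small disconnected components (below 5% of the
   referenced vertices) are dropped from the input surface — residual
   background fragments that survived the point filters.

## Registration and fusion

**Deformation graphs.** Both the accumulated model and the new input
surface are coarsened by incremental isotropic remeshing (split edges
longer than 4/3·L, collapse shorter than 4/5·L with link-condition,
length and fold guards, valence-improving flips, tangential Laplacian
smoothing with re-projection onto the original surface; boundary edges
are never collapsed and boundary vertices move only along the boundary).
Every graph vertex is a keypoint and carries its nearest source-surface
vertex (`source_map`). The graph edge length defaults to 4× the voxel
resolution.

**SHOT description.** Each keypoint gets a Signature of Histograms of
Orientations: a local reference frame from the eigen-decomposition of the
radius-weighted support covariance (signs disambiguated toward the
support majority using continuous moments — count-based disambiguation
ties on symmetric discrete patches and breaks rigid invariance), a
2 radial × 2 elevation × 8 azimuth spatial partition, and an 11-bin
histogram of the cosine between each support normal and the keypoint
normal, linearly interpolated along the cosine axis; the 352-vector is
L2-normalized. Descriptors are exactly invariant to rigid motion of the
patch.

**Matching.** Keypoints are matched by mutual nearest neighbors
(bidirectional search), ties toward the lower index. Inside the pipeline,
where consecutive frames are known to move little, the descriptors are
augmented with weighted keypoint positions (weight 0.32/L) before the
mutual search, and pairs with implausibly large spatial displacement
(beyond 3× the median pair displacement, floored at 2L) are dropped. Both
measures exist because pure shape matching is ill-posed on nearly
symmetric structures — a uniform ribbon is translation-symmetric along
its own axis and a stem is rotation-symmetric, so mutual SHOT pairs can
connect distant look-alike regions and tear the deformation. The pure
descriptor route remains available through `match_bidirectional()`
directly.

**SR-ARAP deformation.** Matched keypoints propagate to the model surface
(each matched graph keypoint drives its mapped source vertex toward the
matched displacement) and become hard positional constraints. The model
then minimizes the smoothed-rotation as-rigid-as-possible energy
$$E(S') = \sum_i \sum_{j \in N(i)} \big[\, w_{ij}\,
\lVert (v'_i - v'_j) - R_i (v_i - v_j) \rVert^2
+ \alpha A\, \lVert R_i - R_j \rVert_F^2 \,\big]$$
with cotangent weights $w_{ij} = \cot\theta_A + \cot\theta_B$
(boundary edges use their single opposite angle; non-positive sums are
clamped to $10^{-6}$ to keep the Laplacian positive definite), $\alpha$
defaulting to 0.01 and $A$ the surface area recomputed per call so the
smoothness term is scale-invariant. Minimization alternates a **local**
step — per-vertex rotations via the orthogonal-Procrustes solution on the
weighted 1-ring, with the neighbor-rotation coupling term added to the
cross-covariance before re-projection onto SO(3), swept Gauss-Seidel so
each update is the exact coordinate minimizer — and a **global** step
solving the sparse cotangent-Laplacian system for the free vertices
(pre-factored Cholesky, constraints eliminated). Both half-steps are
exact coordinate minimizers, so the energy trace is provably
non-increasing; a Jacobi-style sweep would be marginally simpler but
cannot guarantee that. With $\alpha = 0$ the solver is classic ARAP.
Disconnected components holding no constraint are translated rigidly with
their nearest constrained component, with a warning.

**TSDF fusion.** Both surfaces are converted to sparse truncated
signed-distance volumes: every voxel centre within the truncation $t$
(default 5 voxels) of the mesh stores the signed distance to the nearest
triangle, normalized by $t$ and clamped, plus a linear confidence weight
$1 - |d|/t$. The sign comes from triangle normals oriented toward the
camera (single-view capture makes that unambiguous); closed synthetic
meshes can use the winding instead. Open sheets need one extra rule:
beyond a sheet's rim the nearest feature is a boundary edge and the
"signed distance" keeps flipping sign across the sheet's extension plane,
so the zero set would grow sideways flanges about 0.75·t wide. Voxels
whose closest feature is a boundary edge and whose centre lies laterally
beyond the rim by more than one voxel therefore get zero weight, and the
weight-positive extraction rule skips them. Volumes are fused by weighted
averaging per voxel, voxels observed by only one volume passing through —
that is how newly visible regions accumulate. The warped model's weights
are scaled by 0.4 before fusion: a deformed historical surface carries
more uncertainty than a fresh observation, and the scaling keeps the
fused zero crossing tracking the current frame where both observe the
same region. Marching cubes (constructive per-cube polygon extraction;
ambiguous faces always separate the negative corners, a per-face rule
that is crack-free across neighboring cubes) extracts the new model, a
light outlier/smoothing pass runs, and the surface is regenerated
isotropically so model complexity stays bounded across frames. After the
last frame the model gets a final smoothing, outlier and isotropic
remeshing pass.

## Sensor fusion

Each sensor reading $s_i$ at mounting height $h_i$ maps to an RGB stop by
per-channel linear interpolation on its variable's ramp,
$c(x) = c_{min} + \frac{x - x_{min}}{x_{max} - x_{min}} (c_{max} - c_{min})$,
with out-of-range values clamped. Vertices then interpolate
piecewise-linearly between the bracketing height stops (clamping outside
$[h_1, h_n]$), one model copy per variable. Default ramps: temperature
blue→red over 15–40 °C, humidity white→blue over 20–90 %RH, luminosity
black→yellow over 0–60 klx; bytes round half-up. The optical camera frame
has y pointing down, so the default height axis is `-y`; it is
configurable because a world-vertical transform may be applied upstream.

## The synthetic test bed

The generator builds a corn-like plant — a capped-cylinder stem (0.4 m
tall, 30 mm diameter by default) with four arching ribbon leaves
(0.22 × 0.05 m, rising about 35° and drooping toward the tip) — with
per-vertex part labels and leaf coordinates as ground truth. Animation
rotates each leaf about its attachment by
$A \sin(2\pi f t + \phi)$, blended linearly from root (fixed) to tip
(full angle), so vertex correspondence across time is the identity index
map. Frames are rendered by perspective-correct z-buffer rasterization at
the conditions of a consumer stereo depth camera: the plant about 0.4 m
away, Gaussian depth noise (σ = 2 mm), background spanning roughly
0.3–23 m (a far wall, small sparse strips of "other plants" at 0.4–1.6 m
behind the subject sized so the outlier and small-component filters can
remove them, and a small near object). Sensor profiles follow the
qualitative field orderings: plants inside a row have stronger base-to-top
gradients (darker, cooler, wetter base); sunny conditions are uniformly
hotter, drier and brighter than cloudy ones.

What passing tests on this bed do show: the full chain — conditioning,
surfacing, graph matching, SR-ARAP alignment, TSDF fusion — closes the
loop on a moving plant with realistic noise, recovers ground-truth plant
height to within two voxels, accumulates occluded regions once visible,
and degenerates gracefully to rigid fusion on static scenes. What they do
not show: performance on real field scans, whose leaves carry fine
geometric texture (veins, serration) that makes SHOT far more
discriminative than on these smooth ribbons, but which also bring
calibration error, motion blur and mixed pixels that the renderer does
not emulate.

## Numerical choices and problem sizes

Sizes used by the bundled tests and acceptance checks were chosen to keep
a full run comfortably on one CPU: end-to-end sequences render at 320×240
(13 frames) or 160×240-class resolutions with 4–6 mm voxels; unit fixtures
use hundreds to a few thousand points. At full 640×480/3 mm settings the
same code paths run unchanged, only longer. Other numerics: PCA
neighborhoods flag collinear cases (second eigenvalue below 10⁻⁹ of the
largest) as invalid rather than fabricating a normal; remeshing splits
only edges that are the longest in every incident triangle per pass
(guaranteeing conformity); the kd-tree breaks distance ties toward the
lower index so every query is deterministic; SR-ARAP stops at
`max_iterations` (default 15 in the pipeline) or when the energy falls
below 10⁻⁶ of its initial value; marching cubes welds vertices through
global lattice-edge keys so extracted surfaces are watertight wherever
the volume is. The pipeline contains no random number generation — given
identical frames and configuration its PLY output is byte-identical; all
synthetic-data randomness is seeded explicitly.

## Known limitations

Single-viewpoint capture leaves the far side of every organ unobserved,
so "watertight" is aspirational on real data; stems reconstruct as
half-tubes. Keypoint matching degrades on symmetric or featureless
geometry and the spatial augmentation then dominates, which assumes small
inter-frame motion (fast gusts between sparse keyframes would need
coarse-to-fine alignment). Height-gradient colorization encodes only one
variable per model copy; composite encodings are out of scope. The TSDF
grid is axis-aligned and shared across frames through a fixed origin;
a camera moving between frames would first need ego-motion compensation,
which the pipeline does not attempt.
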
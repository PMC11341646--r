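---
title: "Estimating 3D muscle fascicle orientations: models, parameters and design choices"
author: "penna3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 3D muscle fascicle orientations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(penna3d)
```

## The problem

Pennation angle — the angle between a muscle fascicle and its aponeurosis —
links muscle architecture to force-generating capacity. In B-mode
ultrasound, fascicles themselves are dark; what is visible is the bright
perimysium sheathing them. `penna3d` implements a complete workflow that
turns a stack of pose-tracked 2D B-mode frames into a per-voxel 3D fascicle
direction field and per-compartment pennation summaries, and validates the
chain on synthetic scenes with exactly known ground truth.

The pipeline, in order:

1. **Reconstruction** (`defineGrid()`, `reconstructVolume()`): frame pixels
   are mapped through their rigid poses into a reconstruction grid whose
   axes come from a PCA of the frame corner cloud; pixels are binned to
   their nearest voxel (collisions averaged) and remaining holes take the
   value of their nearest filled voxel. Temporal alignment between video
   and tracking is estimated by `estimateTimeOffset()` (detrended
   normalized cross-correlation).
2. **Vessel enhancement** (`applyMVEF()`): intensities outside the
   compartment mask and inside the aponeurosis mask are zeroed; every
   sagittal slice is filtered with a single-scale Frangi vesselness filter
   and the slices are re-stitched into a 3D volume rescaled to 0–255.
3. **Direction detection** (`directionField()`): after a 3D Gaussian blur,
   the per-voxel Hessian is diagonalized; the eigenvector of the
   smallest-*magnitude* eigenvalue is the fascicle direction (along a
   bright tube the second derivative vanishes along the fibre and is
   strongly negative across it).
4. **Pruning cascade** (`fascicleMask()`, `scaleAndPruneLengths()`,
   `pruneEndpoints()`): binarization at 10% of the maximum filtered value
   (tie kept), erosion of the compartment mask, anisotropic scaling of the
   unit eigenvectors by the voxel spacing with removal of vectors shorter
   than 50% of the field maximum, and removal of voxels with fewer than 18
   non-empty 26-neighbours.
5. **Smoothing and fill** (`smoothField()`, `fillMuscle()`): penalized
   least-squares smoothing of the surviving vector components (s = 35),
   then — for muscle data — linear interpolation plus a light second
   smoothing pass (s = 0.5) to cover the whole compartment.
6. **Quantification** (`aponeurosisDirection()`, `pennationAngles()`,
   `compartmentSummary()`, `phantomAngles()`, `muscleVolume()`).

## The vesselness model

For a 2D slice, the scale-normalized Hessian (Gaussian derivatives at scale
$\sigma$, responses multiplied by $\sigma^2$) has eigenvalues
$|\lambda_1| \le |\lambda_2|$. The vesselness is

$$V = \exp\!\left(-\frac{(\lambda_1/\lambda_2)^2}{2\beta^2}\right)
      \left(1 - \exp\!\left(-\frac{\lambda_1^2+\lambda_2^2}{2c^2}\right)\right),$$

set to zero wherever $\lambda_2 \ge 0$ (bright-on-dark polarity; a vanishing
$\lambda_2$ carries no ridge evidence). Parameters and defaults:

* `sigma` — Gaussian scale in *pixels of the slice grid*: 2 for muscle
  volumes, 3.5 for phantom volumes. The in-plane anisotropy of the sagittal
  slice (e.g. 0.17 vs 0.66 mm) is deliberately *not* compensated inside the
  2D filter; the filter operates in pixel units, the convention of the
  widely used vesselness implementations. Directions are converted to
  physical units later, by the
  spacing multiplication of step 4.
* `beta = 0.5` — blob suppression.
* `c = 15` — structure sensitivity, calibrated to 0–255 intensities; this
  is why readers rescale wider-typed sources on load.
* Single-scale evaluation: although the filter family is "multiscale", one
  scale per data type is specified and used.
* $\gamma = 2$ scale normalization is adopted from the original vesselness
  formulation; it matters only if a multi-scale variant is configured.

Whether slice intensities should be re-normalized per slice before
filtering is an open choice; the package filters slices as they are (one
global 0–255 rescale after re-stitching), which keeps the filter response
comparable across slices of one volume.

## The smoother

Each vector component $y$ on its grid is smoothed by minimizing
$\|W^{1/2}(z-y)\|^2 + s\,\|Lz\|^2$ with $L$ the discrete Laplacian under
reflective (Neumann) boundaries. In the DCT-II eigenbasis of $L$ the solve
is diagonal, $\hat z = \mathrm{IDCT}(\Gamma \odot \mathrm{DCT}(y))$ with
$\Gamma = (1 + s\Lambda^2)^{-1}$; missing voxels get weight 0 and a
fixed-point iteration (over-relaxation factor 1.75) converges to the exact
solution of the weighted normal equations — the test suite checks agreement
with a sparse direct solve to 1e-8 on grids up to $20^3$. An optional
robust mode applies bisquare reweighting of residuals. Numerical
tolerances: iteration stops at relative change `tol` (default 1e-3,
tightened in tests) or `maxIter` (default 100).

`s = 35` for the detected field and `s = 0.5` for the extrapolation pass
are the pipeline defaults; `s = 0` with no missing data is the
identity, and constants are fixed points at any `s`.

## Geometry conventions

One affine everywhere: world (mm) = `origin + axes %*% (index * spacing)`
with 0-based indices, first index fastest. Directions produced by the
Hessian stage live in index space; multiplying componentwise by the voxel
spacing converts them to physical directions (this is also what makes the
50%-length pruning orientation-dependent on anisotropic grids — a literal
behaviour that is kept as the default).
Eigenvector signs are canonicalized to the hemisphere with positive
component along the muscle long axis (ties: +z, +y, +x), so sums and means
of directions are stable. The missing-voxel marker is NaN in all three
components, distinct from the zero vector.

`muscleFrame()` orders principal axes by decreasing variance and
`rotateVolume()` resamples so the muscle long axis lies along +z (the
sagittal fascicle plane becomes yz); the resampling grid is kept
right-handed by flipping the new x axis when necessary, which makes an
identity frame an exact no-op.

## Pruning-cascade choices

* Binarization tie at exactly the 10% threshold: kept (inclusive).
* Erosion structuring element: 6-connected, iterated `shrinkVoxels` times
  (default 10 for muscle, 0 for phantom — the phantom masks contain no
  epimysium to avoid).
* Neighbourhood for endpoint removal: full 26-connectivity, single
  simultaneous pass, voxels with *exactly* 18 non-empty neighbours
  survive.
* "Smallest eigenvalue" is interpreted as smallest magnitude; a
  literal-signed mode (`directionField(mode = "signed")`) is available for
  auditing — for a bright ridge the signed minimum is perpendicular to the
  fibre, which is visibly wrong on the synthetic scenes.
* Near-degenerate voxels (isotropic blobs, eigenvalue gap below 5% of the
  largest magnitude) are flagged, not removed; the flag map can be
  exported from the CLI.

## The synthetic scenes

The generators are first-class, tested code and define the validation
conditions; their defaults are chosen once, on physical grounds.

**Wire phantom** (`generateWirePhantom()`): two groups of 0.1 mm wires — a
3 x 6 array and a 2-wire pair on a 2.5 mm hole pitch — run nearly along the
sweep axis, tilted symmetrically in the xz-plane so the inter-group angle
is exactly 10.78 degrees by construction. Voxel spacing is
0.14 x 0.14 x 0.37 mm. The generator's `wallSeparation` default of 24 mm is
the length of wire a single probe field of view captures, which keeps a
replicate at roughly 200 x 59 x 66 voxels; the physical phantom's walls are
much further apart, but only the imaged section matters for direction
recovery. Water is modelled as nearly anechoic (intensity 4 on 0–255):
water carries no scatterers, and a bright water background would create a
step edge at the compartment-mask boundary that the vesselness filter
would enhance as strongly as the wires themselves.

**Pennate muscle** (`generatePennateMuscle()`): a superellipsoid envelope
(semi-axes 9 x 6.5 x 19 mm — wider than deep, as muscle cross-sections
are, which also keeps the cross-section principal axes well separated)
with a central aponeurosis sheet at y = 0 (thickness 0.8 mm, direction +z)
separating a superficial (default 5 degrees) and a deep (default 10
degrees) compartment. The bright perimysium is modelled as a lattice of
tubes along the programmed fascicle direction (2.4 mm pitch both across
the yz-normal and along x, 0.6 mm width): fascicle bundles are tubular,
and a tube gives the Hessian one near-zero eigenvalue along the fibre,
where an extended sheet would leave a degenerate in-sheet eigenpair and an
ill-defined direction. Spacing 0.17 x 0.17 x 0.66 mm.

**Noise model** (`addSpeckle()`): anisotropic Gaussian PSF (axial 0.2 mm,
lateral 0.4 mm — the lateral value also serves as the elevational beam
width, which is what spreads a thin wire across neighbouring slices),
multiplicative Gaussian noise (sigma 0.08) as a log-compressed-speckle
surrogate, additive noise (sigma 2), clipped to 0–255. This stresses the
detector with realistic blur and intensity fluctuations but is *not* a
physical acoustic simulation: no directional scattering, shadowing,
attenuation, or angle-dependent specular response. Passing tests on these
scenes therefore demonstrates correctness of the algorithmic chain and its
noise robustness at this noise class, not end-to-end accuracy on clinical
data.

"Low noise", where parameter-recovery checks use it, means the same PSF
with multiplicative sigma 0.02 and additive sigma 1.

## Whole-muscle fill

The fill step interpolates the gridded field linearly and then
extrapolates with the light smoothing pass. Scattered trilinear
interpolation needs a Delaunay backend; instead the package interpolates
componentwise along each grid axis (1D linear interpolation wherever a
missing voxel is bracketed by support along that axis, averaging the
available axis estimates). This is exact for affine component fields on
bracketed voxels — the property the tests pin down — and any voxel not
bracketed along any axis falls through to the `s = 0.5` smoother
extrapolation, which runs in any case. Vectors are re-normalized
after filling; a zero-norm fill (possible only when opposite directions
cancel exactly) falls back to the mean field direction.

## Reconstruction choices

* Collision policy in pass 1: arithmetic mean — order-independent, so
  reconstruction does not depend on frame order.
* Hole fill: iterative 26-neighbour wavefront carrying the physically
  nearest filled value, bounded by `fillRadius` (default 3 voxels); beyond
  the bound a voxel is declared outside the swept region and flagged in
  the coverage mask. This is a grid-geodesic approximation of exact
  Euclidean nearest-neighbour assignment.
* Pose interpolation to frame timestamps: componentwise linear with SVD
  re-orthonormalization — sweeps are near-linear, so slerp is unnecessary.
* Grid axes are assigned to (image x, image y, sweep) by maximal
  parallelism with the PCA eigenvectors, so the requested spacing triple
  means (in-plane, in-plane, slice distance) regardless of which direction
  carries the most variance.

## Validation problem sizes

The phantom study runs 11 replicates (seeds 1–11) of the default phantom at
full pipeline settings; pairwise angle sets larger than the configured cap
(10^7 by default, 2 x 10^6 in the acceptance script) are subsampled with a
seeded RNG and flagged. The pennate-muscle recovery runs one default-size
muscle (about 125 x 96 x 64 voxels). These sizes were chosen so that a
replicate completes in well under a minute while each wire still spans
dozens of voxels per dimension of interest; direction recovery depends on
local tube geometry, not on total volume extent.

Two known biases are worth stating. First, directions detected within the
filter's support of the volume z-faces bend toward the grid axis (the
reflective boundary kinks a tilted tube); interior slabs recover the wire
tilt to better than 0.05 degrees, while the end slabs pull the pooled
mean-direction angle roughly 0.7 degrees below the true inter-group angle.
A real scan shares this effect: the swept volume also ends somewhere, and
wires or fascicles crossing its faces are filtered against the same kind
of artificial boundary. Second, the 50%-length pruning on anisotropic grids preferentially
removes vectors aligned with the fine-spacing axes; for near-sweep-aligned
structures this is benign, but it is the main reason the pruning cascade is
exposed as configuration.

## Known limitations

* Orientations only: no streamline tractography, fascicle length or
  curvature.
* Masks are inputs; no segmentation is provided.
* The NIfTI affine round-trips at single precision (the format stores
  float32); MetaImage round-trips exactly.
* The speckle surrogate does not model angle-dependent specular
  reflection, so aponeurosis-adjacent bias seen in real data is not
  reproduced.
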
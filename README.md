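# penna3d — muscle fascicle orientations from freehand 3D ultrasound

`penna3d` estimates three-dimensional muscle fascicle orientations and
pennation angles from freehand 3D ultrasound. It is written for muscle
physiologists and biomechanists who record pose-tracked 2D B-mode sweeps of
a muscle (for example the tibialis anterior, which has superficial and deep
compartments diverging from a central aponeurosis) and want per-voxel 3D
fascicle directions, per-compartment pennation statistics and muscle
volumes — together with synthetic validation scenes whose ground truth is
known exactly.

## Method

In B-mode images fascicles are dark and the perimysium around them is
bright, so fascicle orientation is recovered from the bright line
structure:

1. **Reconstruction.** Tracked frames are binned into a voxel grid
   (nearest-neighbour assignment, collisions averaged; empty voxels take
   their nearest filled neighbour). The grid axes come from a PCA of the
   frame corner cloud; temporal offset between video and tracking is found
   by cross-correlation.
2. **Vessel enhancement.** Each sagittal slice of the masked volume is
   filtered with a single-scale Frangi vesselness filter. With Hessian
   eigenvalues |λ₁| ≤ |λ₂| at scale σ (σ = 2 px muscle, 3.5 px phantom):

       V = exp(−(λ₁/λ₂)²/(2β²)) · (1 − exp(−(λ₁²+λ₂²)/(2c²))),  β = 0.5, c = 15

   with V = 0 where λ₂ ≥ 0 (bright-on-dark polarity). Slices are
   re-stitched into a 3D volume.
3. **Direction detection.** The re-stitched volume is blurred with a 3D
   Gaussian; per voxel, the eigenvector of the smallest-magnitude Hessian
   eigenvalue is the fascicle direction.
4. **Pruning.** Binarize at 10% of the maximum filtered value, erode the
   compartment mask, scale direction components by the voxel spacing and
   drop vectors below 50% of the maximum length, then drop voxels with
   fewer than 18 non-empty 26-neighbours.
5. **Smoothing and fill.** A DCT-based penalized least-squares smoother
   (s = 35) smooths the surviving vectors; for muscle data, linear
   interpolation plus a light second pass (s = 0.5) fills the whole
   compartment.
6. **Pennation.** θ = arccos(|d·a|) against the aponeurosis principal axis
   a, folded to [0°, 90°]; per-compartment summaries resample 5000 angles.

The synthetic wire phantom (two wire groups at a known 10.78° angle,
0.1 mm wires on a 2.5 mm hole pitch, 0.14 × 0.14 × 0.37 mm voxels) and a
two-compartment pennate muscle (0.17 × 0.17 × 0.66 mm voxels) provide
exact ground truth for validation.

## Worked example

```r
library(penna3d)

ph <- generateWirePhantom(WirePhantomSpec(seed = 1L))
res <- phantomPipeline(ph$volume, ph$truth@masks$A, ph$truth@masks$B,
                       truth = ph$truth@trueAngle)
res$stats
#> PhantomAngleStats: truth 10.78 deg, 1e+07 pairs (subsampled)
#>   MAE 0.697 +- 0.534 deg; mean-direction angle 10.084 deg
```

The phantom's two wire groups subtend 10.78°. Running the full detection
pipeline on one noisy replicate, the mean absolute error over all pairwise
angles between the compartments' detected directions is 0.70°, and the
angle between the two compartments' normed mean directions is 10.08° —
a slight underestimate driven by voxels near the volume faces, where the
filter boundary bends directions toward the sweep axis.

```r
mu <- generatePennateMuscle(PennateMuscleSpec(seed = 1L))
res <- musclePipeline(mu$volume, mu$truth@masks$whole,
                      list(superficial = mu$truth@masks$superficial,
                           deep = mu$truth@masks$deep),
                      mu$truth@masks$aponeurosis)
res@summaries[, c("compartment", "nResampled", "mean", "sd")]
#>   compartment nResampled      mean         sd
#> 1 superficial       5000  5.122262 0.01449255
#> 2        deep       5000 10.055084 0.03590077
```

The programmed pennation angles (5° superficial, 10° deep) are recovered
to about a tenth of a degree from the speckled synthetic muscle.

A thin CLI over the same functions is installed at
`system.file("cli", "penna3d", package = "penna3d")` with subcommands
`reconstruct`, `simulate`, `mvef`, `detect`, `pennation` and
`phantom-stats`.

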
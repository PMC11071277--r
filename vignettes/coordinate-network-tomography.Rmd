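---
title: "Unsupervised coordinate-network reconstruction for cryoET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised coordinate-network reconstruction for cryoET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Single-axis cryo-electron tomography tilts a frozen specimen about one axis
(here fixed as y) and records a projection image at each tilt. Mechanical and
radiation constraints restrict the tilt range, typically to ±60°, so a wedge
of Fourier space perpendicular to the beam is never sampled. Classical
weighted back projection (WBP) reconstructs only the measured region;
the unmeasured wedge manifests as z-elongation, membrane and vesicle tops
and bottoms fading out, and anisotropic resolution.

`cntomo` implements an unsupervised alternative: a small coordinate network
(CN) `G_θ : R³ → R` represents the volume as a continuous function, and its
weights are optimized so that the *reprojections* of the network's volume
match the measured tilt series. Nothing is pretrained; the only data the
optimization ever sees are the projections themselves. The network's smooth,
low-frequency-biased parametrization acts as an implicit prior that
extrapolates plausibly into the missing wedge, which is exactly where WBP
has nothing to say.

# The model

## Forward model

A volume `v ∈ R^{x×y×z}` with values on a voxel grid is mapped to a tilt
series `p ∈ R^{l×x×y}` by a parallel-beam projector `P`: at tilt `t`, a
voxel at offset `(dx, dz)` from the grid center lands at detector
coordinate `u = dx cos t − dz sin t`, and its density is shared linearly
between the two neighboring detector pixels. This voxel-driven "linear
splat" was chosen over ray-driven rotate-and-sum resampling deliberately:
bilinear tents evaluated on a rotated lattice do not form a partition of
unity, so a ray-driven implementation loses or gains up to tens of percent
of the mass of point-like features depending on the tilt, whereas the
splat conserves in-field mass exactly, reproduces the plain z-sum exactly
at 0°, and has an exact adjoint (its transpose), which WBP and the training
gradient both reuse. Because the tilt axis is y, the operator factorizes
over y-slices and is materialized once as a sparse matrix per `(x, z,
angles)` combination.

## Objective

Each reconstruction solves

```
θ* = argmin_θ  MSE(p_sub, P G_θ(C)) + λ R(G_θ(C))
```

where `C` is the normalized coordinate grid of the target (sub)volume. The
norm is fixed as the mean squared error, which links directly to the PSNR
used in evaluation; `λ = 0` by default, with an optional total-variation
regularizer (`R = "tv"`) for noisier use cases. Optimization is full-batch
Adam — every iteration evaluates the whole subvolume grid — which makes the
loss trace exactly reproducible for a given seed and keeps the best-loss
iterate well defined; the best iterate, not the last, is returned, making
the fit robust to late-iteration oscillation.

## Network

The network is a four-hidden-layer, 256-feature (by default) fully
connected net with sinusoidal activations `sin(ω₀ ·)` and a positional
encoding that concatenates the raw coordinate with `sin/cos(2^k π c)` for
`k = 0 … K−1`. Defaults `K = 6` and `ω₀ = 30` follow the established
sinusoidal-network initialization scheme: first-layer weights uniform in
`±1/fan_in`, deeper layers uniform in `±sqrt(6/fan_in)/ω₀`. The raw
coordinates are kept alongside the encoding (the cheap, conservative choice
where either convention would do).

The linear output layer is initialized to zero, so the untrained network is
exactly the zero volume. This matters more here than in ordinary scene
fitting: limited-angle projection has a large null space (the missing
wedge), and any initialization noise living in that null space is never
corrected by the data — it would simply persist into the final
reconstruction as structured noise, precisely in the region the method is
supposed to fill gracefully. Starting from the zero volume puts unmeasured
Fourier components at zero, exactly as WBP does, so whatever the converged
network contains in the wedge was produced by the network's own smoothness
bias rather than left over from random weights. Empirically the zero start
also conditions the optimization better (the reprojection residual at a
fixed iteration budget drops severalfold). The conventional random output
layer remains available via `init_network(..., out_init = "siren")`.

Nominal capacity is accounted as `hidden_layers × width²` (the
hidden-to-hidden weights only; 4 × 256² = 262,144 for the default), and
this is the count used for the parameter-to-measurement ratio. The full
trainable count including input/output layers and biases is available via
`count_parameters()` and recorded in logs.

## Slab partition and learned initialization

Large tomograms are not fit with one network. The volume is divided into
y-axis slabs of width `j` chosen so that nominal parameters per subvolume
voxel stay at a fixed ratio (default 1/8): `j = params / (ratio · x · z)`,
rounded and clamped to `[1, y]`. A 1024×1024×256 volume with the default
network yields 128 slabs of width 8. The printed worked example forces the
1/8 reading of the ratio — 262,144 parameters against 1024·8·256 =
2,097,152 measurements — and that is the convention implemented.

Slabs are fit in y-order. The first starts from random initialization and
runs `iters_first` iterations (default 2000) with the learning rate decayed
logarithmically (geometrically) from 1e-3 to 1e-4. Every later slab is
*warm-started* from the previous slab's fitted weights and runs
`iters_rest` iterations (default 400) from 1e-4 down to 1e-5.

Coordinate normalization interacts with the warm start in a way that is
easy to get wrong. x and z are normalized to [-1, 1] per subvolume (slabs
share the full x-z extent, so this is also the global map), but y uses the
*whole-volume* [-1, 1] axis, each slab receiving its own narrow window of
it. With a global y axis, a warm-started network evaluated on the next
slab's coordinates yields its own *continuation* across the slab boundary
— approximately correct wherever an object spans the seam, which is the
whole point of chaining. Had each slab instead been rescaled to its own
[-1, 1] (the obvious alternative), the warm start would predict the
previous slab's content at the new slab's location; measured on the desk-
scale benchmark this makes a warm start *worse* than a cold one. The chain
runs through all slabs without restarts. Slab estimates are concatenated with no overlap or blending;
y-streak artifacts at slab boundaries are a known cost of this choice, and
`single_network = TRUE` avoids them whenever the volume is small enough to
fit with one network.

Adam moments are not carried across slabs: the optimizer restarts fresh on
each subvolume so that every slab solves the same kind of problem, only
from a better starting point.

## WBP baseline

The in-repo baseline ramp-filters each frame along the detector axis
(|f| weighting in Fourier space), back-projects with the exact adjoint of
the projector, and scales by the angular spacing in radians. It is a
generic textbook WBP, not a replica of any specific package's apodization;
comparisons against it are therefore about the presence or absence of
missing-wedge information, not about implementation parity with IMOD.

# Evaluation metrics

All metrics compare a reconstruction `v̂` against the known ground truth
`v*`; higher is better.

* **PSNR** `= 10 log10(Im²/MSE)` with `Im = 1` for [0,1]-normalized
  volumes. (A common printed form omits the square on `Im`; with the
  denominator explicitly defined as the MSE, the standard squared form is
  what is implemented.)
* **SSIM**: mean local structural similarity with a 3D Gaussian window
  (size 11, σ = 1.5, clipped for small volumes), standard stabilizers,
  averaged where the full window fits.
* **VIF**: pixel-domain multi-scale visual information fidelity (4 scales,
  Gaussian-scale-mixture channel model, HVS noise σ² = 2 on a 0-255
  rescale). Full 3D GSM modeling is out of scope: VIF is computed on the
  central half of the z-slices and pooled across slices and scales. Values
  below 1 indicate information loss (blur), above 1 contrast enhancement.
* **FSC**: per-shell normalized correlation of the Fourier transforms,
  computed without mean subtraction, shells of half-unit membership from
  radius 1 to Nyquist.
* **Directional FSC**: the same correlation restricted to Fourier voxels
  labeled *present* (within half a frequency unit of some acquired
  central-section plane, i.e. `min_t |k · n̂(t)| ≤ 0.5`) or *missing* (the
  complement — the wedge). Nearest-voxel labeling is used; shells keeping
  fewer than 10 labeled voxels are dropped rather than reported as zero.
  The missing-region curve is the headline metric: WBP, by construction,
  has essentially no information there, so any genuine correlation is
  extrapolation earned by the reconstruction prior.

Reconstructions carry arbitrary intensity scales (WBP depends on filter
normalization; the CN fits [0,1]-normalized projections), so the
voxel-based metrics are computed after least-squares affine registration
(`a·v̂ + b`) to the reference. FSC is scale-invariant and computed
unregistered. Min-max rescaling was rejected for this purpose because WBP's
filter over/undershoots would compress its effective range and bias the
comparison against the baseline.

# Phantoms

The generator reproduces the two in-silico test volumes used to
characterize the method, at any grid size:

* **Hollow spheres**: binarized spherical shells of constant density,
  diameters uniform in a configurable range, centers uniform inside the
  grid, non-overlapping. Shell thickness defaults to 2 voxels (the value is
  not dictated by anything physical; it merely keeps shells visible after
  smoothing). A voxel belongs to a shell iff `r_in ≤ |x − c| < r_out`.
* **Mixed shapes**: an eight-family mixture (full spheres, ellipsoids,
  pyramids, cubes, rectangular prisms, discs, 4- and 6-pointed crosses),
  axis-aligned, binarized, placed by rejection sampling that forbids
  overlap and touching. Box-like extents use half-open intervals so an
  integer side covers exactly that many voxel planes.

Both recipes are finished with a Fourier low-pass (default Gaussian rolloff
at 0.25 Nyquist) to smooth the binarized surfaces, and projections are
jointly min-max normalized to [0, 1]. A hard rolloff is also provided; it
is the idempotent variant and the one that fully empties the stopband
(a Gaussian rolloff wide enough to be meaningful on a small grid
necessarily leaks power past the cutoff).

What these phantoms deliberately do *not* model: noise, the contrast
transfer function, alignment errors, or real molecular density. Passing
tests on them demonstrates correct geometry and genuine wedge
extrapolation on piecewise-smooth objects; it does not promise
performance on experimental tilt series.

# Desk-scale study conditions

The test suite and the acceptance script reproduce the head-to-head
comparison at desk scale, chosen so a single CPU finishes in minutes: a
64³ grid with 8 hollow spheres of diameter 8-24 voxels (the reference
recipe's 16-64 px on a 1024-px grid scales below the voxel size), tilts
±60° every 2° (61 projections), a width-16 network, and 500/100 iterations
with the reference learning-rate schedules. At the fixed 1/8 parameter-to-
measurement ratio the width-16 network partitions the volume into 32 slabs
of width 2. The width was picked to preserve the operative *regime* of the
reference geometry rather than any single number: slabs much thinner than
the objects spanning them (reference: 8-voxel slabs against 16-64-voxel
spheres), which is the premise that makes each warm start a near-
continuation of the previous subvolume. `spheres_benchmark()` runs exactly
this experiment.

Two desk-scale caveats are worth stating plainly, because they shape what
the test suite can and cannot show. First, the scaled iteration budget
(500/100) limits how deeply warm-started slabs can fit: at the reference
schedules a content-bearing middle slab stalls several-fold above the loss
it reaches when given a full 500-iteration cold fit, so the desk-scale
reconstruction carries a larger reprojection residual and more slab-seam
striping than a full-budget run would. Second, slab 1 abuts the volume
edge, where the placement margins of the phantom leave little content, so
its (500-iteration) loss is near-trivially small compared to
content-bearing warm slabs. The missing-wedge directional FSC comparison
against WBP — the property the method exists for — is robust to both
effects; voxel-global scores such as PSNR are not, and at this scale WBP's
conservative linear estimate can win them.

# Numerical choices and edge cases

* Voxel centers sit at 0-based integer coordinates, x fastest; normalized
  coordinates map index `i` of an n-voxel axis to `2(i−1)/(n−1) − 1`.
* The tilt axis is y everywhere; positive tilt rotates the beam from +z
  toward +x. A fixture pins this sign convention.
* `angles_from_params(α, β)` refuses non-divisible step/range combinations
  rather than silently truncating.
* Rays leaving the detector are dropped (vacuum framing, no wrap).
* Training runs in double precision; the compiled engine
  (RcppArmadillo) and the pure-R reference engine produce loss traces that
  agree to machine precision, and the R engine remains the implementation
  of record for regularized objectives.
* Divergence (non-finite loss) aborts with the slab index and the tail of
  the loss trace.
* Degenerate inputs fail loudly: constant stacks cannot be normalized,
  constant references have no VIF, empty Fourier shells are dropped with a
  warning.
* MRC I/O is a self-contained MRC2014 reader/writer (modes 0/1/2, both
  endiannesses on read, float32 little-endian on write).

# Known limitations

* Hard slab concatenation leaves y-streaks at slab boundaries
  (single-network mode avoids them at small scales).
* The CN underperforms at the highest frequencies relative to its
  low/mid-frequency gains — the implicit prior is a low-frequency one.
  VIF, which emphasizes high frequencies, can favor WBP on some inputs.
* No noise or CTF modeling; real tilt series are out of scope.
* Slabs are processed sequentially to preserve the learned-initialization
  chain; the design keeps them embarrassingly parallel if the chain is
  given up.
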
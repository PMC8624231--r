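---
title: "Methods: MR pre-processing models, parameters and validation phantoms"
author: "mriprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MR pre-processing models, parameters and validation phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriprep)
```

# Scope

`mriprep` enhances skull-stripped 3D brain MR volumes ahead of automated
tumor segmentation. It implements four classical enhancement operators —
Gibbs ringing removal by local sub-voxel shifts, iterative bias field
correction in the log domain, intensity normalization (z-score and Nyul
landmark mapping), and block-based 3D adaptive histogram equalization — and
composes them into ten named sequences, the most important being `seq6`:
bias correction followed by ringing removal. Everything is validated offline
on synthetic phantoms with known ground truth; no training data, no
downloads, no learned components.

# Gibbs ringing removal

## The artifact

An MR scanner acquires a finite window of k-space. Reconstructing on the
grid matching that window convolves the ideal image with a sinc-like kernel,
so every sharp interface is flanked by oscillations whose period is two
voxels (the Nyquist period of the reconstruction grid) and whose first
overshoot is roughly 9 % of the edge step.

## The method

For each image line, the package evaluates `2 * numShifts + 1` sub-voxel
resamplings `line(x + s)`, `s = t / (2 numShifts)`, realized exactly through
the Fourier shift theorem. For every voxel it selects the shift minimizing
the total absolute first difference over the windows `[minWindow, maxWindow]`
on either side of the voxel, taking the smaller of the two sides, and then
interpolates the chosen resampling linearly back onto the original grid. At
the optimal shift the samples straddle the zero-crossings of the ringing
kernel, so the oscillation is sampled out rather than smoothed out.

In 2D, both in-plane directions are unrung separately (`jx`, `jy`) and
recombined in k-space as `FT^-1 { FT(jx) Gx + FT(jy) Gy }` with

$$G_x = \frac{1 + \cos k_y}{(1 + \cos k_y) + (1 + \cos k_x)},
  \qquad G_y = 1 - G_x .$$

`Gx` is large where `|ky|` is small, i.e. at frequencies whose ringing runs
along x, which is exactly where the x-direction pass is trustworthy. Because
`Gy` is stored as `1 - Gx` the normalization `Gx + Gy = 1` is exact in
floating point, so artifact-free content (`jx = jy`) passes through
bit-faithfully up to FFT round-off. Volumes are processed slice by slice
over a configurable plane (default axial, the first two storage axes; the
processing plane is not dictated by the data, so it is a parameter).

## Numerical choices

* Shift candidates are ordered `0, -1, +1, -2, +2, ...`; ties in the
  oscillation measure resolve to the earliest candidate. Constant or
  artifact-free signals therefore select the zero shift and are returned
  unchanged, not merely approximately reproduced.
* Oscillation windows wrap circularly, consistent with the periodicity the
  FFT-based shifts impose.
* For even-length axes the Nyquist coefficient's shift phase is replaced by
  its real part (`cos(pi s)`), keeping shifted lines real.
* All FFTs run in double precision; after the 2D recombination the imaginary
  residue is checked against `1e-8` of the signal range.
* Defaults `numShifts = 20`, windows `[1, 3]` follow the reference
  implementation of the sub-voxel shift method.

## What sub-voxel shifts cannot do

The shift search covers at most half a voxel, so it can cancel oscillations
only near the two-voxel Nyquist period. The package's `addGibbsRinging()`
simulates truncation by *zero-filling*: it zeroes high-frequency
coefficients but keeps the grid, which produces ringing at period
`2 / keepFraction` voxels. For any `keepFraction < 1` that period exceeds
two voxels and is **out of reach of the method by construction** — a
property worth knowing before applying the tool to zero-filled
(interpolated) clinical data. The physically faithful simulation is
`makeRingedPhantom()`, which renders the scene on an in-plane supersampled
grid and crops k-space to the target shape, exactly what an acquisition
does; its ringing sits at the Nyquist period and is removable. The
validation suite uses `makeRingedPhantom()` for removal quality and
`addGibbsRinging()` for the spectral contracts (identity at full k-space, DC
preservation, the 9 % step overshoot against a brute-force DFT oracle).

## How removal quality is measured

On a piecewise-constant phantom the band-limited image cannot represent the
interface voxels themselves: whatever resampling is applied, a voxel
straddling a sharp boundary carries an irreducible error of up to half the
step. Whole-mask RMSE is therefore dominated by a thin interface shell and
is insensitive to the ringing. The suite's *ringing-quantification mask* is
the brain support minus a 2-voxel dilated shell around tissue interfaces;
the same mask is used for the before and after RMSE, so the reported
reduction measures exactly the removal of ringing. The suite requires a
reduction of at least 50 % at 25 % in-plane k-space truncation of a 128^3
phantom, and a sub-1 % change on an un-truncated phantom.

# Bias field correction

## Model

The observed image is modeled multiplicatively, `V = u * f`, with `u` the
true image and `f` a smooth, strictly positive field (coil and B0
inhomogeneity). Taking logs on the strictly positive mask gives the additive
model `v = u + f`. The field is estimated iteratively:

$$\hat u_n = \hat u_{n-1} - S\{\, \hat u_{n-1} - E[\hat u \mid \hat u_{n-1}]\,\},$$

where `E[u | v]` comes from sharpening the log-intensity histogram
(deconvolving an assumed Gaussian blur by Wiener filtering, then taking the
conditional expectation of the sharpened density under that blur) and `S` is
a mask-aware Gaussian smoothing. The total field estimate is the running sum
of the per-iteration residuals, and the corrected image is `V / exp(f_e)`.
Two bookkeeping identities hold to floating point after every run and are
asserted by the tests: the log field equals the sum of residual log fields,
and on the mask the log corrected image plus the log field equals the log
input.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `maxIterations` | 50 | iteration cap |
| `convergenceThreshold` | 0.001 | CV of the ratio between successive field estimates |
| `histogramBins` | 200 | log-intensity histogram resolution |
| `sharpenFWHM` | 0.15 | assumed blur FWHM, as a fraction of the masked log range |
| `wienerNoise` | 0.01 | Wiener deconvolution noise constant |
| `smoothingScale` | NA | Gaussian FWHM in mm; NA = 1/3 of the smallest masked extent |

`smoothingScale` is interpreted as the FWHM of the smoothing kernel, not its
sigma: a sigma of a third of the brain extent attenuates the very field
being estimated so strongly that the convergence criterion fires after one
essentially empty iteration. The FWHM reading preserves enough update
amplitude for geometric convergence while still suppressing anatomy.

## Scale convention

The multiplicative model identifies `f` only up to a global constant.
Each smoothed residual is demeaned over the mask before accumulation, which
pins the estimated field to unit geometric mean on the mask; the overall
intensity scale of the input stays in the corrected image. The synthetic
field generator uses the same identifiable parameterization: its log-field
is standardized to zero mean over the volume with maximum magnitude
`log(amplitude)`, hence lies within `[1/amplitude, amplitude]`.

## Stopping

Besides the prescribed convergence criterion (CV of `exp` of the current
residual below `convergenceThreshold`), the loop stops when that CV improves
by less than 5 % from one iteration to the next. A genuinely field-like
residual keeps shrinking geometrically; histogram spread that no smooth
field can remove (noise, texture, residual ringing) regenerates the same
small residual every iteration, and without the guard those contributions
accumulate into an unbounded field drift. The guard leaves clean-bias
trajectories untouched (they hit the threshold first) and halts drift-prone
ones near their correlation optimum.

## Assumptions and limitations

* The histogram sharpening assumes tissue classes separated in log intensity
  by more than the assumed blur (`sharpenFWHM` x masked log range). Three
  well-separated classes (CSF, gray matter, white matter at roughly
  40 / 80 / 130) satisfy this comfortably; six or more classes spanning the
  same range mathematically cannot, and highly unbalanced class sizes make
  the practical limit stricter. The bias-quality phantoms are therefore
  three-class; with many close tissue classes a smaller `sharpenFWHM` is
  appropriate.
* Single-resolution iteration with a Gaussian smoother; no multi-scale
  pyramid and no B-spline machinery. The smoother sits behind the
  `smoothField()` interface and is swappable.
* Voxels with non-positive intensity carry no log-domain information and are
  excluded from the mask rather than clamped (skull-stripped backgrounds are
  exact zeros).

# Intensity normalization

`zscoreNormalize()` maps masked voxels to zero mean, unit variance, and pins
unmasked voxels to 0 so the background remains the dominant class for
downstream segmentation. It is idempotent and invariant under affine
intensity transforms.

`nyulTrain()` computes each training volume's scheduled percentiles (default
1, 10, ..., 90, 99) on the mask, maps the (p1, p99) span affinely onto the
standard range (default 1–100), and averages the mapped landmarks across
volumes; because the span mapping is affine, affinely related training
volumes contribute identical landmarks. `nyulApply()` maps a volume's own
percentiles piecewise-linearly onto the model landmarks, extending the
terminal segments' slopes beyond (p1, p99). The mapping is non-decreasing
and idempotent after the first application. Duplicate percentile abscissae
(piecewise-constant data) are collapsed before interpolation. In
`runSequence()` a `nyul` stage without a supplied model trains on the input
volume itself — self-normalization onto the standard scale; cohort
normalization should train one model and pass it explicitly.

# Adaptive histogram equalization

The volume is partitioned into `tiles` blocks (default 8 x 8 x 4: square
in-plane tiles and coarser through-plane blocks, matching the stacked-slab
reading of block-based 3D equalization). Each block's histogram over the
*global* intensity range yields the mapping
`out = gmin + (gmax - gmin) * cdf(bin)`; each voxel is transformed by
trilinear interpolation among the mappings of its eight surrounding block
centers, with boundary blocks replicated. Design notes:

* With one tile the transform reduces *exactly* to global histogram
  equalization — global equalization degrades MR images visually and is not
  recommended as a stage, but the degenerate case provides an exactness
  oracle for the tiled implementation and is asserted bitwise in the tests.
* A block whose histogram occupies a single bin maps by identity, so
  constant volumes (and flat blocks) pass through unchanged.
* The optional `clipLimit` caps each block histogram at `clipLimit` x block
  voxel count and redistributes the excess uniformly, bounding how far
  near-constant regions are stretched (contrast-limited variant). The
  default is plain, unclipped equalization.
* Whether the original block construction interpolated between slabs in 3D
  cannot be determined from its description; the tiled-3D reading with
  trilinear mapping interpolation reproduces all stated ingredients (blocks
  of slices, per-block histograms, trilinear reconstruction) and is the
  standard construction.

# Segmentation metrics

`diceScore()` is the set overlap `2|A∩B| / (|A|+|B|)`, with the empty-empty
case defined as 1 (both masks agree on absence; conventions vary across
evaluation tools, so this is stated explicitly). `regionDice()` derives the
nested evaluation regions from the BraTS label dialect — whole = {1, 2, 4},
core = {1, 4}, enhancing = {4} — and scores each. `multiclassDiceLoss()`
implements the soft multiclass dice loss

$$L = -\frac{2}{K} \sum_{k} \frac{\sum_i l_{ik} m_{ik}}
      {\sum_i l_{ik} + \sum_i m_{ik}},$$

with `l` the per-voxel class scores and `m` the one-hot truth, bounded in
[-1, 0], equal to -1 exactly at perfect one-hot agreement and 0 at complete
disagreement. No smoothing epsilon is added; a class with an all-zero
denominator contributes 0, which covers the degenerate case without
perturbing the formula. Where the surrounding text of the source formula
swaps the roles of the two symbols, the explicit definition (scores =
softmax output, one-hot = truth) is followed; the loss value is symmetric in
the binary case anyway.

# Sequences

`presetSequence()` provides the ten named recipes. In `seq2` Gibbs removal
precedes bias correction, while the starred rows `seq6`–`seq8` run bias
correction *first* — the only reading under which the two rows differ, and
the one matching their prose descriptions. `seq9` and `seq10` repeat the
Gibbs-only recipe of `seq1` (they differ only in the dataset they were
evaluated on, which is outside this package's scope). `runSequence()`
applies stages strictly in order, shares one mask across mask-aware stages,
and returns a `RunRecord` with per-stage parameters and masked mean/sd
before and after — enough to re-run identically and to compare stages
numerically. Multi-modality (4D) inputs are processed channel by channel
with per-channel normalization statistics.

# The phantom generator

`makePhantom()` renders rotated ellipsoids into a piecewise-constant volume
with the BraTS geometry as default (240 x 240 x 155 voxels, 1 mm isotropic)
and a three-level nested tumor (labels 2 / 1 / 4 for edema / core /
enhancing, nested by construction through scaled semi-axes). A 2 % seeded
jitter on centers, semi-axes and levels makes different seeds produce
different but statistically equivalent phantoms, bitwise reproducible under
a fixed seed. Default tissue levels (40 / 80 / 130, lesion 180 / 230 / 290)
follow typical FLAIR contrast ordering: dark CSF, mid gray matter, brighter
white matter, bright lesion.

What the phantoms emulate: piecewise-constant tissue with sharp interfaces,
acquisition-truncation ringing (`makeRingedPhantom()`), smooth multiplicative
bias (`addBiasField()`, Gaussian bump or low-order polynomial), Gaussian and
Rician noise (`addNoise()`), zero background as after skull stripping. What
they do not emulate: anatomical geometry, partial-volume ramps at
interfaces, spatially varying noise, multi-coil effects, motion, or
partial-Fourier acquisition. Passing the suite therefore demonstrates the
operators' mathematical correctness and their behavior in their design
regimes, not performance on any specific clinical dataset.

For pipeline experiments the doubly-corrupted phantom is ringed, then
multiplied by a bias field, then re-masked to the brain support — the order
in which a real image is acquired and then skull-stripped. Without the
re-masking, background ringing oscillations enter the positive-voxel mask
and their logarithms dominate the bias histogram.

# Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` use a 128^3 phantom for ringing
removal quality, 64^3 and 48^3 three-class phantoms for bias recovery and
sequence comparisons, 100^3 volumes for noise statistics, and lines up to
length 64 against the brute-force shift-search oracle (200 random lines).
These sizes were chosen so that each quantity is estimated on at least tens
of thousands of voxels while the whole suite remains a desk-scale
computation.

# Known limitations

* Sub-voxel shift unringing does not correct zero-filled (interpolated)
  data, and unringing along the through-plane axis is not attempted.
* Bias correction assumes a few well-separated tissue classes (see above);
  it is single-resolution and Gaussian-smoothed, so it is not a bit-for-bit
  reimplementation of the canonical B-spline tool.
* The interface shell of a sharp phantom is irreducibly mis-represented
  after band-limiting; quality metrics exclude it and real-data edge
  behavior (slight blur at interfaces) should be assessed visually.
* Dice results reported alongside the original ten-sequence study require
  training a 3D U-Net on BraTS data and are out of scope here; this package
  provides the pre-processing, phantom validation and metric layer.
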
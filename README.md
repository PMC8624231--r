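# mriprep

Pre-processing of volumetric brain MR images for tumor segmentation:
Gibbs ringing removal, bias field correction, intensity normalization,
adaptive histogram equalization, composable pipelines, segmentation
metrics, and a synthetic phantom generator for fully offline validation.

## Who this is for

Researchers preparing skull-stripped, co-registered brain MRI (BraTS-style
FLAIR/T1/T1ce/T2 volumes in NIfTI) for automated tumor segmentation, and
anyone who needs a quantitatively validated implementation of the classical
MR enhancement operators on 3D volumes in R.

## The methods

**Gibbs ringing removal (local sub-voxel shifts).** Truncated k-space
acquisition leaves sinc oscillations around sharp interfaces. Each image
line is resampled at 2·M+1 fractional shifts s = t/(2M), realized by the
Fourier shift theorem; per voxel, the shift minimizing the local total
variation (windows [1, 3] on the less-oscillating side) samples the ringing
at its zero-crossings, and the value is linearly interpolated back to the
grid. The two in-plane passes jx, jy are recombined in k-space as

    J = FT⁻¹{ FT(jx)·Gx + FT(jy)·Gy },
    Gx = (1 + cos ky) / ((1 + cos ky) + (1 + cos kx)),  Gy = 1 − Gx,

so `Gx + Gy = 1` exactly and artifact-free images pass through unchanged.

**Bias field correction (iterative, log domain).** Under the multiplicative
model V = u·f, the log field is estimated by alternating histogram
sharpening (Wiener deconvolution of an assumed Gaussian blur of the
log-intensity histogram, then the conditional expectation E[û | û]) with
mask-aware Gaussian smoothing:

    ûₙ = ûₙ₋₁ − S{ ûₙ₋₁ − E[û | ûₙ₋₁] },   f̂ₑⁿ = Σᵢ f̂ᵣ,ᵢ ,

and the corrected image is V / exp(f̂ₑⁿ). The bookkeeping identities
(field = sum of residual fields; corrected · field = input on the mask)
hold to machine precision.

**Intensity normalization.** Z-score (zero mean, unit variance on the brain
mask) and Nyul landmark normalization (percentile landmarks mapped
piecewise-linearly onto a standard 1–100 scale).

**3D adaptive histogram equalization.** Per-block histogram CDF mappings
with trilinear interpolation between block centers; one block reduces
exactly to global equalization; optional contrast limiting.

**Sequences.** `presetSequence("seq1")` … `"seq10"` compose the stages; in
`seq6` bias correction runs *before* Gibbs removal, the composition that
generalizes best.

**Metrics.** Per-region dice (whole / core / enhancing from BraTS labels
{0, 1, 2, 4}), the multiclass soft dice loss (−1 at perfect agreement), and
masked RMSE / PSNR / mean-ratio image quality.

## Worked example

Corrupt a phantom with acquisition-style ringing (25 % k-space) and a
25 % bias field, then run the recommended sequence:

```r
library(mriprep)

spec <- phantomSpec(shape = c(64, 64, 44), seed = 11)
rp   <- makeRingedPhantom(spec, keepFraction = 0.25)
bf   <- addBiasField(rp$ringed, biasFieldSpec(amplitude = 1.25, scale = 25, seed = 3))
arr  <- volData(bf$volume); arr[volData(rp$clean) == 0] <- 0   # skull-strip
corrupt <- mriVolume(arr)

out <- runSequence(corrupt, presetSequence("seq6"))
out$record
#> RunRecord for 'seq6' (mriprep 0.1.0)
#>  stage meanBefore sdBefore meanAfter sdAfter elapsed
#>   bias      104.5    32.60     102.3   21.27   1.459
#>  gibbs      102.3    21.27     101.9   21.11   1.274

round(rbind(before = imageQuality(corrupt,    rp$clean, volData(rp$clean) > 0),
            after  = imageQuality(out$volume, rp$clean, volData(rp$clean) > 0)), 3)
#>          rmse   psnr meanRatio
#> before 15.071 25.513     1.101
#> after  13.092 26.735     1.074
```

The bias stage pulls the masked sd from 32.6 back to 21.3 (the clean
phantom's tissue contrast) and the mean-ratio toward 1; the Gibbs stage
then removes the ringing oscillation. Whole-brain RMSE improves modestly
because it is dominated by the thin interface shell that band-limited data
cannot represent; the methods vignette explains the interface-excluded
ringing metric on which removal is ≥ 50 %.

Per-region dice between two label maps:

```r
regionDice(rp$labels, rp$labels)
#>     whole      core enhancing
#>         1         1         1
```

A command-line wrapper with subcommands `run`, `phantom`, `unring`,
`biascorrect`, `normalize`, `ahe`, `evaluate` is installed at
`exec/mriprep`, e.g.

```sh
Rscript exec/mriprep run --sequence seq6 --input in.nii.gz --output out.nii.gz
```

## Package layout

- `R/phantom.R` — phantom generator, ringing/bias/noise corruption
- `R/gibbs.R` — weight filters, 1D/2D/3D sub-voxel-shift unringing
- `R/biasfield.R` — histogram sharpening, field smoothing, iterative correction
- `R/intensity.R` — z-score, Nyul train/apply, 3D AHE
- `R/metrics.R` — dice score, region dice, multiclass dice loss, image quality
- `R/pipeline.R` — presets, sequence runner, NIfTI I/O, YAML configs
- `vignettes/mriprep-methods.Rmd` — models, assumptions, parameter rationale
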
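# shapecut

Fully automatic coarse-to-fine segmentation of a single organ in 3D scalar
volumes (CT-like images), built for the classic hard cases of abdominal CT:
neighboring organs at near-identical intensity, internal low-attenuation
lesions, and intensity inhomogeneity.

The pipeline has two stages:

1. **Multi-atlas initialization.** Pre-warped atlas pairs (intensity +
   binary label, already registered onto the target grid by an external
   tool such as elastix) are ranked by normalized mutual information,
   r_i = NMI_i / max_j NMI_j, atlases with r_i ≥ φ (default 0.8) are kept,
   and their labels are fused by weighted majority voting with ω_i = r_i.
2. **Iterated shape-constrained graph cut.** From the current shape Φ₀ an
   unsigned anisotropic distance field is built; interior voxels deeper
   than Φs = 25 mm become hard source seeds, the exterior beyond
   Φt = 35 mm becomes the sink, and on the band in between the energy

       E(L) = Σ_p ( α·D_p(L) + β·J_p(L) + γ·S_p(L) ) + Σ_{p,q} B_pq(L_p,L_q)

   is minimized exactly by s–t min-cut (Boykov–Kolmogorov) and iterated
   with shape updates (α = β = 10, γ = 80, 5 iterations). D is a
   2-channel Gaussian data term (intensity + blurred intensity), J an
   LBP-three-orthogonal-planes texture term scored by the L1 Wasserstein
   distance between windowed cumulative code histograms, S = 1 − e^(−d/r₀)
   an exponential shape leash, and B an edge term attenuated by the Earth
   Mover's Distance between spin-image-like descriptors so cuts prefer
   *texture* interfaces even where intensity is flat.

Volumes are read/written as NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage
(`.mhd`/`.mha`); evaluation implements Dice and the MICCAI'07 liver
measures (VOE, SRVD, ASD, RMSD, MSD). A synthetic phantom generator with
ground truth and jittered atlas pairs makes the whole pipeline testable
without any external data.

## Worked example

Generate the hardest canonical phantom (64³, 2 mm voxels: an organ with an
adjacent structure of *identical* mean intensity, separated only by
texture), fuse its three jittered atlases, and refine:

```r
library(shapecut)

case  <- generate_phantom(standard_specs(17)[[1]])
fused <- fuse_atlases(case$image, case$atlases)
fused$scores
#>        nmi         r selected    weight
#> 1 1.019347 0.9980949     TRUE 0.9980949
#> 2 1.021293 1.0000000     TRUE 1.0000000
#> 3 1.019752 0.9984909     TRUE 0.9984909

cfg <- shapecut_config(window_mm = c(10.5, 10.5, 14))  # physical window
seg <- segment_volume(case$image, fused$mask, cfg = cfg)
seg$diagnostics
#>   iteration   energy dice_prev n_source n_band reverted
#> 1         1 409885.8 0.7419230      198 224761    FALSE
#> 2         2 283512.5 0.9396761      306 198354    FALSE
#> 3         3 282103.8 0.9993795     1244 202336    FALSE
#> 4         4 281795.8 0.9999354     1284 202362    FALSE
#> 5         5 281791.1 1.0000000     1284 202362    FALSE

evaluate_segmentation(fused$mask, case$truth)[c("dice", "msd_mm")]
#> $dice   [1] 0.7599
#> $msd_mm [1] 26.68
evaluate_segmentation(seg$mask, case$truth)[c("dice", "msd_mm")]
#> $dice   [1] 0.9410
#> $msd_mm [1] 8.25

base <- segment_intensity_only(case$image, fused$mask)
dice(base, case$truth)
#> [1] 0.9251806
```

Reading: the fused initialization (Dice 0.76, worst surface error 27 mm —
calibrated to realistic registration residual) is refined to Dice 0.94
with the worst surface error down to 8 mm; the classical intensity-only
graph cut on the same seeds reaches 0.93 and leaks along the
equal-intensity interface that the texture and shape terms resolve.
`dice_prev` tracks convergence (agreement of consecutive shapes), and
`n_source`/`n_band` the automatic seed and band sizes.

## Command line

```sh
inst/cli/shapecut phantom  --case 1 --seed 17 --out-dir case1/
inst/cli/shapecut fuse     --target case1/image.nii.gz \
    --atlas-intensity case1/atlas1_img.nii.gz,case1/atlas2_img.nii.gz,case1/atlas3_img.nii.gz \
    --atlas-label     case1/atlas1_lab.nii.gz,case1/atlas2_lab.nii.gz,case1/atlas3_lab.nii.gz \
    --out case1/init.nii.gz --scores case1/scores.json
inst/cli/shapecut segment  --target case1/image.nii.gz --init case1/init.nii.gz \
    --out case1/seg.nii.gz --diagnostics case1/diag.json
inst/cli/shapecut evaluate --seg case1/seg.nii.gz --ref case1/truth.nii.gz \
    --out case1/report.json
```

## Documentation

The methods vignette (`vignettes/shapecut-methods.Rmd`) documents the
model, every tunable parameter with units and defaults, the interpretive
decisions in the energy, what the phantom generator does and does not
emulate, and known limitations.
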
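# featwarp

Feature-based deformable registration of 2D/3D scalar medical images
(CT-like volumes), for image-guided radiation therapy workflows and
anyone who needs a dense displacement field between two phases of a
moving anatomy — e.g. inspiration/expiration volumes of a 4D CT study —
without an iterative intensity optimization.

Instead of optimizing an intensity similarity metric, the method finds
its own landmarks and interpolates them:

1. **Detect** feature points on both images: voxels inside a tissue
   intensity window whose 3×3×3 neighbourhood carries high gradient
   energy `Σ‖∇I‖²`, non-maximum suppressed.
2. **Describe** each point with a SIFT-style signature: the 8×8×8 window
   is split into eight octants, and per octant an 8-bin orientation
   histogram of the in-plane gradient (45° bins, magnitude-weighted) is
   built for each of the xy, yz, zx planes — 192 components.
3. **Match** template and target points by the least-squares descriptor
   difference
   `S = Σ_α |(∇I)_α − (∇I′)_α|²`; with `S₁ ≤ S₂` the two best candidate
   distances, a pair is accepted only when `κ = S₁/S₂ < 0.5`, and a
   bidirectional pass keeps only mutual best matches.
4. **Interpolate** the surviving control points with a thin-plate spline
   (kernel `U(r) = r² log r²`, bordered system `L = [K P; Pᵀ 0]`,
   `L⁻¹Y = (W | a)ᵀ`), densify it into a target→template displacement
   field, and backward-warp the template.

The package also ships digital deformation phantoms with analytically
known ground truth (harmonic warps `x′ = (1 + b cos mq)·x`, smooth
Gaussian-lobe 3D fields, embedded spherical markers), plus evaluation
tools (error fields, exceedance statistics, marker residuals, red/green
fusion overlays), so the whole method is testable end to end without any
external data.

## Worked example

The standard 2D accuracy study generates a textured 170×170 phantom
(2 mm pixels), deforms it with the harmonic warp (`b = 0.13`, `m = 2`,
peak displacement ≈ 18 mm), registers template to target with default
settings, and compares the recovered field with the analytic truth over
the body:

```r
library(featwarp)
st <- harmonic_phantom_study(seed = 1)
print(st$result)
#> <registration_result>
#>   feature points: 1009 template, 1054 target
#>   matches: 562 forward, 460 after bidirectional filter (45.6% of detected)
#>   field: mean |u| 6.01 mm, max |u| 28.50 mm
print(st$report)
#> <error_report> 17496 voxels evaluated
#>   mean error 1.199 mm, max error 14.306 mm
#>   fraction >2mm: 15.24%
#>   fraction >10mm: 0.15%
```

Reading: of ~1000 detected feature points per image, 460 associations
survive the ratio test and the bidirectional filter and become TPS
control points.  Across the 17 496 body pixels the recovered field is on
average 1.2 mm from the truth (the deformation itself averages 4.8 mm,
`st$pre_registration_mean`), and only 0.15 % of pixels are off by more
than 1 cm.  The 3D analogue with embedded spherical markers is
`marker_phantom_study()`; its headline number is the fraction of markers
with registration residual below 2 mm.

Individual stages are available as plain functions
(`detect_feature_points()`, `compute_descriptors()`, `match_forward()`,
`bidirectional_filter()`, `fit_tps()`, `tps_to_field()`,
`warp_image()`), and a thin command-line front end lives at
`inst/cli/featwarp` (`featwarp register --template t.nii --target g.nii
--out-field dvf.mha ...`).  Images travel as NIfTI or MetaImage,
landmarks as `label,x,y,z` CSV or JSON.

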
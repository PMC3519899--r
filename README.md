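# growcutvol

Semi-automatic tumor volumetry for 3D medical images in R: GrowCut
competitive region-growing segmentation from user scribbles, morphological
post-editing, and Dice/volume evaluation with per-case and summary reporting.

## The problem

Volumetric change of cerebral pathologies such as pituitary adenomas drives
treatment decisions, and the clinical reference standard — manual
slice-by-slice contouring on MRI — is slow and user-intensive. A practical
alternative is seeded segmentation: the clinician paints a rough area inside
the tumor and a stroke outside it, an automaton grows the two regions
competitively until they meet, and small residual defects are cleaned up with
binary morphology (dilation, erosion, island removal). The resulting label
map yields the tumor volume directly as *voxel count × voxel volume*, and its
agreement with a reference segmentation is measured with the Dice similarity
coefficient.

## The algorithm

GrowCut models the image as a cellular automaton. Each voxel *p* carries a
label *l_p* (0 unlabeled, 1 tumor, 2 background) and a strength
*θ_p ∈ [0, 1]*. Scribbled voxels are seeds with their class label and
*θ = 1*. At every synchronous iteration each unlabeled or weakly held voxel
is attacked by its neighbors *q ∈ N(p)* (26-connectivity by default) with
force

    a(q → p) = g(|c_p − c_q|) · θ_q,   g(x) = 1 − x / max_diff,

where *c* are intensities and *max_diff* is the maximal neighbor intensity
difference in the region of interest. The strongest attacker conquers *p*
(sets *l_p ← l_q*, *θ_p ← a*) when its force strictly exceeds *θ_p*.
Strengths only increase and are bounded by 1, so the automaton terminates;
iteration stops when no voxel changes.

Three classic speed-ups are built in and provably leave the result unchanged:
computation is restricted to the bounding box of the scribbles plus a margin
(the ROI), the similarity weights are precomputed once and reused, and
saturated voxels (*θ = 1*, or no changed neighbor) are skipped. A naive
reference implementation (`growcut_reference()`) that visits every voxel of
the full grid each iteration serves as correctness oracle: the test suite
checks bit-identical output on randomized instances.

The evaluation half of the package computes DSC = 2|A∩B| / (|A| + |B|),
physical volumes, the per-case/summary report tables (min, max, mean, sample
SD), the classical geometric volume models (spherical π d³/6, ellipsoid
π a b c/6, mean-radius 4/3 π r̄³, caliper a b²/2) and the bidimensional
Macdonald size measure with its ≥ 50 % response criterion. A synthetic
phantom generator (`make_phantom()`, `make_scribbles()`) provides
contrast-enhancing ellipsoid tumors with known ground truth so the whole
pipeline is testable without patient data.

## Worked example

```r
library(growcutvol)

ph  <- make_phantom(preset = "medium", noise_sigma = 10, seed = 42)
sc  <- make_scribbles(ph$truth)     # area inside the tumor + stroke outside
fit <- growcut(ph$image, sc)
fit
#> GrowCut segmentation
#>   grid: 64x64x64 voxels, ROI [13,14,14]..[52,51,51]
#>   seeds: 3912 foreground, 3440 background; max_diff = 159.0231
#>   34 iterations, converged
#>   label 1 (tumor): 6368 voxels
#>   label 2 (background): 51392 voxels

seg <- apply_postedit(mask_of(fit$label_map),
                      list(postedit_step("remove_islands")))
compare_pair(ph$truth, seg, "phantom-42")
#>      case_id volume_manual_mm3 volume_auto_mm3 voxels_manual voxels_auto dsc_percent
#> 1 phantom-42              6368            6368          6368        6368         100
```

The segmented tumor occupies 6368 voxels of 1 mm³, i.e. 6.37 cm³ — a
medium-preset phantom — and at 10 % noise the recovered mask matches the
ground truth exactly (DSC 100 %). On the bundled ten-case pituitary adenoma
study records, the reporting pipeline produces the familiar two-table layout:

```r
study_report(adenoma_records())
#> Summary (volumes in cm^3):
#>  stat volume_manual_cm3 volume_auto_cm3 voxels_manual voxels_auto dsc_percent
#>   min              0.76            1.02        4457.0      5828.0       75.60
#>   max             15.27           15.84      104133.0    108005.0       85.87
#>  mean              6.37            6.47       48082.1     48056.9       81.97
#>    sd              3.96            4.14            NA          NA        3.39
```

A thin command-line front-end over the same functions lives at
`inst/cli/vol.R` (`vol phantom | segment | postedit | evaluate | report`).

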
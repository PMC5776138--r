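# optquant

Quantification of EdU-labelled cell proliferation in 3-D reconstructed
optical projection tomography (OPT) volumes of the adult zebrafish brain.

After a stab lesion to one telencephalic hemisphere, proliferation in the
brain changes in two distinct ways: immune cells (macrophages, neutrophils)
flood the parenchyma around the injury within a day, while the resident
stem/progenitor cells of the periventricular neurogenic niches step up
their division rate over the following days. Whole-brain OPT scans of
EdU-labelled, cleared brains capture both responses at once; telling them
apart is a quantification problem. `optquant` implements three
complementary read-outs on isotropic 16-bit volumes, plus the statistics
and a synthetic phantom generator that makes every stage testable without
any microscope.

## The three analyses

All three operate on the same convention: intensities span [0, 65535],
the stack's pages are 1-pixel virtual cross-sections along the
anterior–posterior (A-P) axis, and voxels are isotropic (edge length
*s* ≈ 4.5–5 µm, voxel volume *s*³ ≈ 91–125 µm³).

1. **Histogram analysis** (`sample_profile`) — a maximum projection
   through the horizontal plane is masked to its non-black pixels
   (intensity > 0) and segmented into 20 µm A-P bins; each bin reports the
   mean EdU intensity of its masked pixels. The result is an A-P
   proliferation profile whose peaks sit over the neurogenic niches.
2. **Structure analysis** (`structure_volume`) — within a box ROI spanning
   a structure's full A-P depth, every voxel is assigned to one of 16
   intensity bins of width 4,096. The black bin (intensity < 4,096) is
   discarded; the pixel count over the 15 non-black bins, times the voxel
   volume, is the structure's EdU⁺ volume in µm³. This measure sees *all*
   labelling, stem cells and immune cells alike.
3. **Slice analysis** (`slice_volume`) — every 5th section through a
   niche, restricted to a per-section demarcation mask and (by default) to
   the first three non-black bins (lower edges 4,096 / 8,192 / 12,288).
   By sampling only the niche and only the dimmer bins it largely excludes
   the bright immune-cell signal, isolating the stem-cell response.

Group statistics follow the field's convention: one-way ANOVA across
treatment groups (control, 1, 3, 7 days post lesion) with Tukey's
post-hoc test at p < 0.05, reported as mean ± SEM (`compare_groups`,
`mean_sem`). Brain-volume morphometry from the autofluorescence channel
is provided by thresholded segmentation (`segment_brain`, `mask_volume`),
and two bench calculators reproduce the staining-solution recipe and the
EdU stock molarity (`scale_recipe`, `stock_molarity`).

## Worked example

Generate a synthetic injury cohort (5 control, 4 × 1 dpl, 4 × 3 dpl,
5 × 7 dpl), measure the lesioned telencephalic hemisphere with structure
analysis, and compare groups:

```r
library(optquant)

spec <- phantom_spec()                       # default injury phantom
coh  <- generate_cohort(spec, seed = 42)     # 18 samples with ground truth
hemi <- phantom_box_roi(spec, "lesioned_hemisphere")

vols <- lapply(coh$samples, structure_volume, roi = hemi,
               roi_name = "lesioned_hemisphere")
print(vols[["control_01"]])
#> structure analysis 'lesioned_hemisphere' | sample control_01 (control):
#>   426 pixels in bins {1,...,15} -> 53250 um^3

tab <- volume_table(vols)
compare_groups(split(tab$volume_um3, tab$group))
#> One-way ANOVA with Tukey post-hoc
#>    group n    mean       sem
#>     1dpl 4 1856625  3222.237
#>     3dpl 4 1732000 11543.960
#>     7dpl 5   94250  4570.626
#>  control 5   73300  5743.556
#> ANOVA: F = 2.172e+04, p = 6.637e-26 (significant at alpha = 0.05)
#>  group_a group_b mean_diff        p_adj significant
#>     1dpl    3dpl   -124625 3.161943e-08        TRUE
#>     1dpl    7dpl  -1762375 3.086420e-14        TRUE
#>     1dpl control  -1783325 3.086420e-14        TRUE
#>     3dpl    7dpl  -1637750 3.086420e-14        TRUE
#>     3dpl control  -1658700 3.086420e-14        TRUE
#>     7dpl control    -20950 1.354263e-01       FALSE
```

Reading the output: the control hemisphere carries ~53,000 µm³ of EdU⁺
signal (constitutive niche proliferation); at 1 dpl the same box measures
~1.85 × 10⁶ µm³ because the diffuse immune response dominates, decaying
through 3 and 7 dpl. `mean_diff` is mean(group_b) − mean(group_a). Running
`slice_volume` with `phantom_niche_roi(spec, "ventricular", "lesioned")`
on the same cohort instead shows a peak at 3 dpl — the stem-cell response
that structure analysis cannot separate from the immune burst.

Real scans enter the same pipeline through a cohort manifest
(`load_manifest` / `load_cohort`; CSV with per-sample TIFF paths, group
labels and pixel size) and ROI JSON files (`read_box_roi`,
`read_niche_roi`). A thin command-line wrapper is installed at
`inst/cli/optquant` (`optquant <command> --config <yaml> [--seed ...]`,
commands `generate`, `profile`, `structure`, `slice`, `morphometry`,
`compare`).

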
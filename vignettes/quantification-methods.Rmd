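---
title: "Quantifying EdU proliferation in OPT brain volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EdU proliferation in OPT brain volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optquant)
```

## The measurement problem

Optical projection tomography of a cleared, EdU-labelled adult zebrafish
brain yields an isotropic 16-bit volume in which EdU fluorescence marks
every cell that passed through S-phase during the labelling window. Two
biologically distinct populations contribute: constitutively cycling
stem/progenitor cells confined to periventricular neurogenic niches, and
— after injury — proliferating immune cells spread diffusely through the
parenchyma. `optquant` implements three intensity-based read-outs that
resolve these signals at different spatial scales, the group statistics
applied to them, and a phantom generator that provides ground truth for
all of it.

All conventions are fixed package-wide: intensities live in [0, 65535]
(a 16-bit image cannot represent 65,536, so 65,535 is "white"); stack
pages are anterior-to-posterior 1-pixel virtual sections, page rows run
dorsal-to-ventral, page columns left-to-right; indices are 0-based with
half-open intervals everywhere, so an ROI's A-P depth is simply
`stop − start`. Voxels are isotropic: a single pixel edge length
(4.5–5 µm in practice) determines the voxel volume as its cube.

## The intensity quantizer

Structure and slice analysis share one primitive: the 16-bin quantizer.
The 16-bit domain is split into 16 bins of width 4,096 (the "16 colors"
look-up-table convention); bin 0 — the *black bin*, intensities below
4,096 — is treated as background and excluded, leaving 15 non-black bins
labelled by their lower edges (4,096, 8,192, … 61,440). The top bin
additionally absorbs 65,535, since 16 × 4,096 overshoots the domain by
one. Two deliberately distinct "non-black" predicates coexist:

* **non-black bins** (intensity ≥ 4,096) gate the volumetric analyses;
* **non-black pixels** (intensity > 0) gate the histogram analysis mask.

A pixel with intensity 2,000 is a non-black pixel but sits in the black
bin. Keeping both predicates, each attached to its analysis, avoids
silently redefining either measure.

## Histogram analysis (A-P profile)

`sample_profile` collapses the volume by a maximum projection along the
dorsal-ventral axis, masks the projection to intensity > 0, partitions
the A-P axis into segments of `segment_um` (default 20 µm, a parameter),
and reports each segment's mean intensity over masked pixels. Design
choices that were genuinely open:

* **Mask-then-mean.** The mean is taken over non-black pixels only, not
  over all pixels of the segment; an all-pixel mean would vary with
  brain width rather than labelling intensity. The alternative reading
  (include zeros inside the footprint) is exposed as the
  `nonblack_only = FALSE` toggle.
* **Empty segments report 0**, not `NA`, so profiles stay plottable and
  comparable; `percent_change` still refuses to divide by a zero control
  mean and flags those segments `undefined` instead of emitting a number.
* **Segment assignment** follows `floor(edge / segment_um)` on each
  pixel's anterior edge. With 4.5 µm pixels segments then hold 4 or 5
  pixels (boundaries fall mid-pixel); the trailing partial segment is
  kept and flagged rather than dropped, since age-matched brains end at
  slightly different lengths.
* **Group aggregation** aligns profiles at the anterior end and
  truncates to the shortest profile — no registration or warping. This
  mirrors the reliance on age-matching; anatomical correspondence beyond
  that is out of scope.

## Structure and slice analysis

`structure_volume` bins every voxel of a box ROI across its full A-P
depth and converts the pixel count over `bins_used` (default: all 15
non-black bins) to µm³. With the default bins this equals thresholding
at 4,096 — a property the tests exploit as a brute-force oracle.

`slice_volume` samples a niche every `stride`-th section (default 5),
restricts each sampled section to its demarcation mask, and uses by
default only the first three non-black bins (4,096–16,383). The bin
subset targets the dimmer stem-cell labelling; bright immune-cell signal
lands in higher bins and is excluded. Further choices:

* **Sampling anchor.** "Every 5th section" needs an anchor; sampling
  starts at the first section of the niche interval (relative index 0),
  which is deterministic and covers the anterior boundary.
* **No stride rescaling.** The reported volume is that of the sampled
  voxels only. Comparisons are within-method, so the constant 1/stride
  factor cancels; an explicit `extrapolate = TRUE` multiplies by the
  stride for users wanting whole-niche estimates.
* **Bin subset inclusivity.** The default subset {1, 2, 3} includes the
  bin labelled 12,288, i.e. intensities up to 16,383.
* At stride 1 with full masks and equal bin subsets, slice analysis and
  structure analysis are the same measurement; this equivalence is
  asserted in the tests.

## Morphometry

Brain-volume measurements from the autofluorescence channel use a
transparent thresholded segmentation (`segment_brain`): a fixed
intensity or Otsu's method on the full 16-bit histogram, optionally
keeping only the largest 26-connected component to drop detached debris.
Volumetry of this kind is commonly done in commercial rendering suites
whose algorithms are undisclosed; a parameter-explicit threshold is the
reproducible alternative, and agreement with any particular commercial
tool is not claimed. A constant volume (nothing to separate) yields an empty
mask rather than an error.

## Group statistics

`compare_groups` runs one-way ANOVA followed by Tukey's HSD
(Tukey–Kramer standard errors for unequal group sizes, the usual case
with n = 4–10 brains per group), significance at α (default 0.05).
Pairwise records are emitted even when the omnibus test fails, flagged
with the omnibus outcome, so downstream tables are never silently empty.
All-identical data (zero variance) produce a defined "no test" outcome —
`NA` statistics, nothing significant — rather than an exception. Each ROI
is tested independently across the four groups; no correction across
ROIs is applied. The test suite cross-checks the Tukey adjusted p-values
against an independent studentized-range computation built from group
means, the pooled mean square and `ptukey`, and verifies the ANOVA's
null type-I error on simulated Gaussian cohorts.

## The phantom generator

`phantom_spec` / `generate_sample` / `generate_cohort` produce synthetic
volumes with ground truth. The model, simplest-that-suffices at every
step:

* the brain is a solid ellipsoid of uniform autofluorescence;
* each niche is a geometric region (midline band, dorsal shell, dorsal
  band) holding a Poisson number of hard-edged spherical EdU foci
  (count ~ rate × region volume, uniform positions, constant peak
  intensity 12,000 — deliberately inside the slice-analysis bin subset);
* the injured state adds diffuse parenchymal intensity outside the
  niches: a focal component confined to the lesioned (left)
  telencephalic hemisphere (9,000 / 4,500 / 500 at 1 / 3 / 7 dpl) and a
  milder brain-wide component (5,000 / 1,200 / 0), both zero in
  controls; ventricular-niche focus rates are boosted ×2.5 ipsilaterally
  at 3 dpl and ×2.2 contralaterally at 1 dpl, while tectal and
  cerebellar rates never change;
* a global Gaussian blur (σ = 3 µm) stands in for the OPT point-spread
  and reconstruction smoothing, followed by additive Gaussian noise
  (σ = 600) and clip-quantization to [0, 65535]. Shot noise is not
  modelled: the phantom emulates *reconstructed* data, not raw
  projections.

Ground truth (focus counts, focus voxels, parenchymal voxels, brain
voxels) is recorded before blur and noise. Determinism is strict:
identical spec, group and seed give bit-identical volumes, and cohort
seeds derive per-sample seeds arithmetically (recorded in the manifest).

The default grid is 80 × 48 × 48 voxels at 5 µm — a desk-scale caricature,
roughly a tenth of a real scan per axis, sized so that a full
50-replicate cohort study runs in minutes. Amplitudes and rates were
chosen once, by pilot simulation, to realize the documented qualitative
injury pattern at strong but non-degenerate effect sizes (niche focus
fill ~10%, so rate boosts translate into proportional volume changes
rather than saturating). `phantom_niche_roi` erodes its demarcation
masks by one in-plane voxel by default, as a human analyst draws
conservatively inside a niche; without the erosion, boundary voxels
blurred from 9,000-amplitude parenchyma would contaminate the 1-dpl
niche measurement.

What passing phantom tests do **not** show: performance on real OPT
reconstructions with anisotropic artifacts, vasculature and pigment
autofluorescence, mis-oriented mounts, or anatomically realistic niche
geometry. The phantom validates the arithmetic and the statistical
machinery, not the imaging.

## Numerical and degenerate-input conventions

* 8-bit input stacks are upscaled by 257 (not 256) so 255 → 65,535
  exactly; the read/write round trip for 16-bit stacks is bit-exact.
* `bin_of` clamps only the closed top end (65,535 → bin 15); any value
  outside the domain is an error naming the offending value.
* Profile peaks use `which.max` (first maximum wins on ties).
* The Gaussian blur truncates its kernel at 3σ and renormalizes at the
  array edges, so constant regions stay constant.
* Ellipsoid-phantom volumetry is asserted to within 2% of the analytic
  volume for semi-axes ≥ 20 voxels (digitization error shrinks with
  size).
* Problem sizes in the shipped tests: 32³ random ROIs (50 of them) for
  oracle equivalence, 200 seeds for Poisson-rate recovery, 2,000
  simulated cohorts for the type-I error, 50 replicate cohorts for the
  injury-pattern study — all chosen as the smallest sizes at which the
  asserted tolerances are comfortably meaningful.

## Limitations

Anisotropic voxels, multichannel interleaved TIFFs, tomographic
reconstruction, anatomical registration and automatic niche segmentation
are out of scope; masks and ROIs are explicit inputs, as the original
demarcations were manual. The statistical layer covers exactly what the
study design used — one-way ANOVA with Tukey — not mixed models or
nonparametric alternatives.
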
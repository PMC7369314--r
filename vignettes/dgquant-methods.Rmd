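---
title: "Quantifying adult hippocampal neurogenesis with dgquant: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adult hippocampal neurogenesis with dgquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgquant)
```

## The problem

Studies of adult neurogenesis in the rodent dentate gyrus (DG) quantify
immunolabelled cell populations along three largely independent axes:

1. **Counting** — how many immunoreactive (-ir) cells are visible in a
   fluorescence micrograph (Sox2 for neural stem cells, and analogous
   markers)?
2. **Stereology** — how do per-section profile counts and traced areas
   become region-level totals, volumes, and densities (BrdU- or Ki67-ir
   cells per mm\(^3\) of granule cell layer, split into dorsal and ventral
   DG)?
3. **Phenotyping and trajectories** — what fraction of birth-dated (BrdU-ir)
   cells co-express maturation-stage markers (Sox2, DCX, NeuN), how do the
   resulting densities and percentages evolve over 2 h, 24 h, 1, 2 and 3
   weeks after division, and how do the sexes differ?

dgquant implements all three stages as composable functions plus a
ground-truthed synthetic-data generator, so the whole pipeline can be
validated end to end without access to microscope data.

## The counting algorithm

`count_cells()` reproduces a classic automated counting recipe for
epifluorescence micrographs in which labelled somata appear as bright,
roughly circular blobs over an uneven background:

1. convert to 8-bit grayscale (`to_grayscale()`, luminance weights
   0.299/0.587/0.114);
2. estimate the background as the **grayscale morphological opening** of the
   image with a flat disk of radius 10 px, roughly the average cell size
   (`estimate_background()`): opening removes every bright structure
   smaller than the disk — i.e. the cells — and keeps the illumination
   field;
3. subtract the background and re-contrast, repeating the subtraction of
   the *original* background image `n_subtractions` times (default 4,
   useful range 3–5; `subtract_and_enhance()`);
4. binarize (Otsu's threshold computed over ROI pixels by default), label
   connected components (8-connectivity by default), and discard components
   smaller than `size_min_px` or larger than `size_max_px`
   (`binarize_and_filter()`).

The result reports the cell count, the ROI area, and the summed cell area
in pixels, with the parameters echoed for provenance.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `disk_radius_px` | 10 px | structuring-element radius; set to the average cell radius |
| `n_subtractions` | 4 | subtraction/contrast passes; 3–5 give equivalent counts |
| `threshold` | Otsu | binarization rule over ROI pixels; fixed override available |
| `size_min_px`, `size_max_px` | 31, 943 px | 10%–300% of the nominal cell area \(\pi\cdot10^2\) |
| `connectivity` | 8 | component labelling neighbourhood |
| `contrast` | `bright_median` | white-point anchor of the per-pass rescale |
| `smooth_background` | `TRUE` | open a 3×3-median-smoothed copy when estimating the background |

The size bounds are design choices (no published values exist): 10% and
300% of the nominal cell area straddle everything a plausible soma can be,
while excluding speckles and merged clumps.

### Numerical design choices

Two choices deserve explanation, because the naive versions fail in a way
that is easy to miss.

**The contrast operator.** "Contrasting" the background-subtracted image is
underspecified in the verbal description of such pipelines. The obvious
candidate — a linear min–max rescale to [0, 255] — is unstable under the
iterated subtraction: after the first pass every pixel evolves as
\(x \mapsto s\,(x - b)\), where \(b\) is the pixel's local background and
\(s = 255/\mathrm{hi}\) the rescale gain. With the min–max choice only the
single brightest pixel is pinned at 255; for every other cell the map has
slope \(s > 1\) with its fixed point at or above the ceiling, so the cell
*decays geometrically* — cells on the bright side of the illumination
gradient vanish by pass 4–5. dgquant therefore anchors the white point on
the **median of the pixels in the upper half of the intensity range** (the
bright, cell-like population): roughly half of every cell core saturates at
255 on each pass, the renewed subtraction is exactly compensated for all of
them, and faint structures (noise, non-specific debris) still decay. The
plain min–max rescale is retained as `contrast = "minmax"` for comparison.

**The background and the noise floor.** The opening of a *raw* noisy image
sits on the lower envelope of the noise (the erosion dips about two
standard deviations below the local illumination, by different amounts in
different places). Subtracting that biased background leaves a spatially
uneven noise residue that the iterated contrast can amplify. `count_cells()`
therefore estimates the background from a 3×3 median-smoothed copy of the
image — the same remedy rolling-ball background subtractors use — while the
image being enhanced and thresholded is never smoothed.
`estimate_background()` itself remains the pure opening (and is verified
against a brute-force erosion/dilation oracle in the test suite), so users
composing the stages manually can make either choice.

Other conventions: components touching the ROI border are kept only if
their centroid lies inside the ROI; a constant image within the ROI yields
zero components (not an error); an empty ROI is an error.

## Stereology

Sections are cut at 30 µm and sampled as a 1-in-10 systematic series, so
the estimated total is the aggregate count times the sampling interval
(`estimate_total()`), and the Cavalieri volume is the summed traced areas
times the 300 µm effective spacing (`cavalieri_volume()`; all µm→mm
conversions live in one internal helper). `cell_density()` returns total,
volume and density together so the identity
`density × volume = total` holds by construction.

Dorsal DG is bregma −1.80 to −4.52 mm and ventral −4.52 to −6.80 mm
(`classify_region()`). The shared boundary is assigned to the ventral
region — the dorsal interval is half-open — so the two regions partition
the range deterministically. Counts refer to one hemisphere and are not
doubled; densities are per counted volume, so the convention cancels.

Image-derived counts (e.g. Sox2 from three micrographs per region) are
reported per ROI *area*, section-series counts per mm\(^3\); the two are
never mixed.

## Phenotyping rules

* `coexpression_pct()` — the sampling estimator: score (a target of) 50
  randomly selected BrdU-ir cells per animal and report the co-expressing
  percentage. Samples below target are used in full and flagged. The
  estimator is unbiased with SD \(100\sqrt{p(1-p)/50}\).
* `double_label_density()` — density of double-labelled cells = BrdU-ir
  density × co-expression fraction.
* `classify_dcx_morphology()` — DCX-ir maturation staging from symbolic
  descriptors (classification was visual in the source workflow, so no
  neurite tracing is attempted): type C iff the apical dendrite branches in
  the molecular layer; else type B iff processes are medium-length or reach
  the molecular layer; else type A.
* `classify_proestrus_estradiol()` — proestrus iff serum 17β-estradiol
  ≥ 50 pg/ml (inclusive, "or higher").
* `classify_proestrus_lavage()` — proestrus iff ≥ 70% nucleated epithelial
  cells in lavage. The source rule ("when 70% of the cells") does not state
  strictness at exactly 70%; dgquant reads it as inclusive and documents
  the choice here.

## Trajectory summaries

`summarize_trajectory()` produces the mean ± SEM table per sex × region ×
time point for one endpoint; SEM uses the sample SD (n − 1) and is absent
(not zero) for singleton groups. `attrition()` is the signed percentage
change of a group mean between two time points. Effect sizes are Cohen's
*d* with df-weighted pooled SD (`cohens_d()`) and partial η²
(`partial_eta_sq()`). Omnibus repeated-measures ANOVA and post-hoc
machinery are deliberately *not* reimplemented: the tidy cohort and summary
tables are designed to be fed to any stats package, and proestrous females
are flagged rather than excluded.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth.

**Micrographs** (`generate_micrograph()`): cells are truncated Gaussian
spots (σ = radius/2, truncated at 2σ so the footprint equals the stated
radius — matching the assumption that the disk structuring element, sized
to the average cell, removes cells completely), placed uniformly at a
minimum pairwise separation (default 4 radii) inside the ROI, over a linear
left-to-right shading (default peak-to-peak 30) plus Gaussian noise
(default SD 8), quantized to 8 bits. Artifacts straddle the size filter:
small ones are 5-px bright speckles; large ones are clumps of overlapping
cell-like spots whose merged area exceeds `size_max_px`. Clumps were chosen
deliberately: broad flat debris is *reconstructed* by the opening and
disappears in the subtraction, so only cell-like clumps genuinely exercise
the max-size filter end to end. Default peak intensity 200 over background
50 reflects a well-stained, non-saturated epifluorescence image.

**Section series** (`generate_section_series()`): a uniform 3-D Poisson
process at the stated density over the full stack; the total is drawn once
and split multinomially across sections in proportion to section volume, so
with interval 1 the counts sum *exactly* to the true total, and systematic
subsampling with a random start leaves `estimate_total()` unbiased.

**Cohorts** (`generate_cohort()`): per-animal densities are log-normal
around the group truth (densities are positive and right-skewed; CV
default 25%), co-label counts are binomial at the 50-cell target, DCX
morphology fractions are multinomial over the DCX-positive subsample, and
hormones are log-normal per animal (female estradiol around 14 pg/ml —
a non-proestrous range — and male testosterone around 1 ng/ml). The
default calibration table (`default_calibration()`) is *illustrative*, not
measured: it encodes the qualitative pattern of the study design — male
BrdU-ir density peaking at 1 week and halving by 2 weeks, a flat female
trajectory, faster male NeuN maturation at 2 weeks with both sexes near 90%
by 3 weeks, a female DCX rise between 2 and 24 h, higher male Ki67, and a
male dorsal / female ventral Sox2 pattern — at magnitudes plausible for rat
DG. Group size defaults to 5 per sex × time (≈ 22 animals per sex over
five time points).

### What the generator does *not* emulate

No point-spread function, chromatic channels, cell-shape anisotropy,
focus drift, or spatially clustered (non-uniform) cell placement; section
areas are supplied, not simulated from anatomy. Passing tests therefore
demonstrate the pipeline's correctness on images whose difficulty comes
from background gradients, noise, and size-filter-straddling artifacts —
not performance on arbitrary real micrographs, where staining variability
and touching cells can dominate.

## Problem sizes used in validation

The test suite regenerates everything from code: micrograph checks use
640×640 images with 5–60 cells (24-image self-consistency batch, 50-image
accuracy suite), the opening is verified against a brute-force oracle on
200 random images up to 64×64, stereology unbiasedness uses 500 simulated
100-section stacks, estimator-recovery checks use 10⁴ binomial/Monte-Carlo
replicates, and cohort recovery uses up to 200 animals per group. These
sizes make every Monte-Carlo tolerance at least ~3 standard errors wide.

## Known limitations

* The counting algorithm assumes bright cells on a darker background; it
  has no notion of touching-cell separation (no watershed), so merged somata
  are removed by the max-size filter rather than split.
* Otsu's threshold presumes a reasonably bimodal ROI histogram; extremely
  sparse fields fall back gracefully (degenerate → zero cells) but
  intermediate pathological histograms are the user's responsibility to
  inspect (`label_map` and `threshold` are returned for that purpose).
* The pixel grid is the only length unit for images; no physical pixel
  size is assumed, so image-derived densities are per-pixel-area unless the
  caller converts them.
* Partial η² is provided as a primitive only; reconstructing published
  ANOVA denominators requires the raw data.
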
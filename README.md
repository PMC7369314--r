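# dgquant

Quantification pipeline for adult hippocampal neurogenesis studies in the
rat dentate gyrus (DG): automated counting of immunoreactive cells in
fluorescence micrographs, Cavalieri stereology over systematic section
series, marker co-expression and maturation phenotyping, and sex × time
trajectory summaries with effect sizes — plus a ground-truthed
synthetic-data generator so the whole pipeline is testable end to end.

It is written for researchers quantifying adult neurogenesis with
birth-dating (BrdU) and stage-specific markers (Ki67, Sox2, DCX, NeuN),
and for anyone who needs a validated, scriptable version of the classic
"morphological opening → iterated background subtraction → binarize →
size-filter" counting recipe.

## The methods in brief

**Counting.** For an 8-bit grayscale micrograph with a region-of-interest
mask, the background is the grayscale morphological opening with a flat
disk of radius 10 px (≈ the average cell size); opening removes every
bright structure smaller than the disk, i.e. the cells. The original
background image is then subtracted from the image `n` times (default 4,
useful range 3–5), re-contrasting after each pass; the result is binarized
(Otsu within the ROI), connected components are labelled, and components
outside [10%, 300%] of the nominal cell area π·10² px are discarded:

count = #{components with size_min ≤ |C| ≤ size_max, centroid ∈ ROI}.

**Stereology.** For a 1-in-10 series of 30-µm sections, the estimated
total is (aggregate count) × 10, the Cavalieri volume is
(Σ traced areas) × 300 µm effective spacing, and density = total / volume
(cells/mm³), reported per dorsal (bregma −1.80 to −4.52 mm) and ventral
(−4.52 to −6.80 mm) DG.

**Phenotyping.** Co-expression percentages come from scoring 50 randomly
sampled BrdU-ir cells per animal (unbiased, SD = 100·√(p(1−p)/50));
double-label densities are BrdU density × that fraction; DCX-ir cells are
staged A/B/C from dendritic morphology descriptors; proestrus is
estradiol ≥ 50 pg/ml or ≥ 70% nucleated epithelial cells in lavage.

**Trajectories.** Mean ± SEM per sex × region × time point (SEM = sd/√n,
absent for n = 1), signed percent change between time points (attrition),
Cohen's *d* with pooled SD, and partial η². ANOVA machinery is
intentionally left to external stats packages; the tables are tidy CSVs.

## Worked example

```r
library(dgquant)

# 1. count cells in a synthetic ground-truthed micrograph
sim <- generate_micrograph(image_spec(n_cells = 20, seed = 1))
count_cells(sim$image, sim$roi)
#> Automated cell count
#>   cells counted : 20
#>   ROI area      : 384400 px
#>   cell area     : 2059 px
#>   parameters    : disk r=10 px, 4 subtractions, otsu threshold, size [31, 943] px, 8-connectivity

# 2. stereology from a per-section table
s <- section_series(data.frame(bregma_mm = c(-2.0, -2.3, -2.6),
                               area_mm2 = c(0.95, 1.02, 0.98),
                               count = c(31L, 44L, 38L)))
cell_density(s, region = "dorsal")
#> Region estimate (dorsal): 1130 cells, 0.885 mm^3, 1276.8 cells/mm^3

# 3. a synthetic cohort and its trajectory
cohort <- generate_cohort(cohort_design(n_per_group = 5, seed = 42))
summ <- summarize_trajectory(cohort, "brdu_density")
summ[summ$sex == "male" & summ$region == "dorsal", ]
#>      endpoint  sex region time_point n  mean    sem
#>  brdu_density male dorsal         2h 5  8189  547.0
#>  brdu_density male dorsal        24h 5 10091  923.0
#>  brdu_density male dorsal         1w 5 16758 2066.1
#>  brdu_density male dorsal         2w 5  7987 1191.4
#>  brdu_density male dorsal         3w 5  7378  690.4
attrition(summ, "male", "dorsal", "1w", "2w")
#> [1] -52.3
```

The counter recovered all 20 planted cells; the ROI and cell areas are the
pixel tallies used for per-area densities. The section table gives
113 × 10 = 1130 estimated cells in 2.95 mm² × 0.3 mm = 0.885 mm³, hence
1277 cells/mm³. The cohort summary shows the designed male trajectory —
a 1-week peak in BrdU-ir density followed by ≈ −50% attrition to 2 weeks
(here −52.3% at n = 5) — and `sex_contrasts(cohort, "brdu_density")`
reports the male–female effect at 1 week (d ≈ 3 under the default
calibration).

Command-line wrappers for batch counting, stereology tables, and
trajectory summaries live in `inst/scripts/` (`dg_count.R`,
`dg_stereology.R`, `dg_trajectory.R`).

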
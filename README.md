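# petruq

Uncertainty analysis of rigid MR-PET registration, and of the PET numbers
computed downstream of it.

## The problem

Neuro-PET quantification — amyloid SUVr in particular — samples a PET image
with regions of interest defined on a T1-weighted MR image and moved into
PET space by a rigid registration. Because PET images are noisy, that
registration is a random quantity: two reconstructions of the same scan
yield two slightly different alignments, hence two different ROI samplings,
hence two different SUVr values. petruq measures this with the
nonparametric bootstrap on the raw event stream: resample the list-mode
data at a chosen count level, reconstruct each replicate with OSEM
(without attenuation correction, attenuation-corrected, or fully
quantitative), register the — optionally randomly mis-positioned — T1w
image to each replicate by normalised mutual information, propagate the
parcellation, and summarise:

* the **Dice coefficient** `DICE = 2|Sr ∩ Sb| / (|Sr| + |Sb|)` of each
  replicate parcellation `Sb` against the gold-standard parcellation `Sr`
  obtained from the full-count registration, with per-ROI standard
  deviations across the replicates as the precision metric;
* the **coefficient of variation of SUVr** (precuneus-analogue target over
  cerebellar-grey reference) under registration jitter alone, with and
  without iterative-Yang partial volume correction;
* **Brown–Forsythe** equal-variance tests comparing design cells.

Everything runs on a seeded digital brain phantom through a parallel-beam
simulator, so the package is self-contained: no data downloads, every
number reproducible from one root seed. Real NIfTI images and parcellations
can be passed through the same functions.

## Worked example

A reduced run — late amyloid-negative frame, AC OSEM with 2 iterations of
14 subsets, bootstrap levels 5% and 60%, five replicates on a 48³ phantom
(a couple of minutes on one CPU):

```r
library(petruq)
library(dplyr)

d <- reduced_design(frames = default_frames()["late_neg"],
                    n_bootstrap = 5L,
                    count_levels = c(0.05, 0.60),
                    grid_shape = c(48L, 48L, 48L))
run <- run_uncertainty_analysis(d, root_seed = 42)

tidy(run$matrix) |>
  filter(roi %in% c("PRC", "CRB_GM", "cortex")) |>
  select(roi, count_level, sd, n, n_failed)
#> # A tibble: 6 × 5
#>   roi    count_level     sd     n n_failed
#>   <chr>        <dbl>  <dbl> <int>    <int>
#> 1 CRB_GM        0.05 0.124      5        0
#> 2 PRC           0.05 0.0950     5        0
#> 3 cortex        0.05 0.0150     5        0
#> 4 CRB_GM        0.6  0.0752     5        0
#> 5 PRC           0.6  0.124      5        0
#> 6 cortex        0.6  0.0202     5        0

run_suvr_propagation(run)$cov
#> # A tibble: 4 × 6
#>   frame    count_level pvc       n suvr_mean    cov
#>   <chr>          <dbl> <lgl> <int>     <dbl>  <dbl>
#> 1 late_neg        0.05 FALSE     5      1.37 0.111
#> 2 late_neg        0.05 TRUE      5      1.15 0.177
#> 3 late_neg        0.6  FALSE     5      1.43 0.0811
#> 4 late_neg        0.6  TRUE      5      1.21 0.129
```

Reading the output: small regions (PRC, CRB_GM) scatter an order of
magnitude more than the whole-cortex union, and SUVr varies by 11% (CoV)
at the 5% count level from registration jitter alone versus 8% at 60%.
Partial volume correction, whose regional means depend sensitively on ROI
placement, amplifies the CoV to 18% while shifting the mean SUVr of this
high-contrast amyloid-negative frame downward, toward the phantom's
uniform-grey-matter truth of 1. Five replicates make the per-region Dice
SDs themselves noisy (PRC's ordering here is a small-sample accident); the
acceptance-scale run — 20 replicates on a 64³ phantom, reproduced by the
test suite — shows the whole-cortex Dice SD dropping about twofold from
5% to 60% counts.

`autoplot(run$matrix)` draws the SD heatmap; `tidy()`/`glance()` methods
exist for the summary objects. A thin CLI covering phantom generation,
design enumeration and the pipelines ships in `inst/cli/petruq.R`.

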
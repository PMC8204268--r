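---
title: "Quantifying the precision of rigid MR-PET registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the precision of rigid MR-PET registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Regional quantification of neuro-PET — for example the standardised uptake
value ratio (SUVr) used in amyloid imaging — relies on region-of-interest
definitions drawn on a T1-weighted MR image and carried into PET space by a
rigid registration. PET images are noisy; the registration that aligns the
T1w image to them is therefore a random quantity, and its variability
propagates into every number computed from the propagated regions. petruq
implements a bootstrap-based pipeline that measures this variability under
controlled conditions: it resamples the raw PET event stream, reconstructs
each replicate, registers the (optionally mis-positioned) T1w image to each
reconstruction, and summarises how far the propagated parcellations scatter
around the registration obtained from the full-count data.

Because raw clinical list-mode data cannot ship with a package, petruq is
simulator-first: a seeded digital phantom plays the role of the subject,
and a parallel-beam projector plays the role of the scanner. Every
mechanism under study — Poisson counting noise, bootstrap resampling,
OSEM convergence/noise trade-off, attenuation and scatter corrections,
NMI-driven rigid registration, partial volume correction — is implemented
for real. What is deliberately simplified is scanner geometry and anatomy;
the consequences are discussed at the end.

## The pipeline

For each design cell (frame x correction mode x OSEM iterations x count
level x engine x replicate):

1. `bootstrap_listmode()` draws `round(f * n)` events with replacement
   from the full-count stream — the nonparametric bootstrap, so each
   replicate emulates an independent acquisition at count level `f`.
   Resampling with replacement is used (rather than thinning) so that the
   100% level is still a new draw from the empirical distribution.
2. `osem()` reconstructs the replicate. The data model is
   `ybar = af * A x + s + r`: attenuation factors multiply the projection;
   scatter and randoms estimates enter the denominator of the
   multiplicative update, never by pre-correcting the counts. NAC mode
   omits attenuation and scatter, AC omits scatter, QNT uses both; randoms
   are corrected in all modes. Subsets are angle-interleaved; the initial
   image is uniform inside the inscribed field-of-view cylinder, making
   reconstructions bit-reproducible.
3. `draw_perturbation()` mis-positions the T1w image by uniform random
   offsets (±10 mm, ±10° per axis by default) applied by pre-multiplying
   its affine, leaving voxel values intact — emulating a PET and MR
   acquired on different days.
4. `register_rigid()` recovers the alignment by maximising normalised
   mutual information, `NMI = (H(F)+H(M))/H(F,M)`.
5. `propagate_labels()` carries the T1w-grid parcellation into PET space
   with the recovered transform and nearest-neighbour interpolation; Dice
   coefficients against the gold-standard parcellation (the one obtained
   with the full-count, unperturbed registration of the same frame and
   engine) quantify the registration scatter.

`run_suvr_propagation()` then samples a single fixed quantitative PET (an
AC reconstruction of a dedicated 30%-count bootstrap — the clinical-static
analogue) with every replicate's parcellation, so that all observed SUVr
variability comes from registration imprecision alone, and repeats the
computation after iterative-Yang partial volume correction.

## The phantom and what it emulates

`make_phantom()` builds a parametric nested-ellipsoid head: a bone shell
(mu = 0.0151/mm at 511 keV), subarachnoid CSF, a cortical grey-matter
ribbon, cerebral white matter (soft tissue mu = 0.0096/mm), ventricles, a
hippocampus-analogue blob, and a cerebellum rendered as a grey-matter
shell around a white-matter core. The ribbon is partitioned into named
regions spanning the size range that matters for overlap statistics: small
patches (ACG, MCG, PCG, HPC, PRC — 50–500 voxels at 2 mm), large lobes
(PRT, TMP) and the residual cortex, plus the cerebellar grey (reference
region) and white matter; the precuneus analogue (PRC) is the SUVr target.

Three geometry choices are deliberate and load-bearing:

* **All three shell semi-axes differ** (head longer front-to-back than
  wide, and wider than tall). A phantom with two nearly equal axes makes
  one rotation an approximate symmetry, and the corresponding registration
  parameter becomes ill-determined — an artefact a real head does not
  have.
* **The cerebellar reference shell is embedded in white matter**, so its
  partial-volume spill couples to the surrounding white matter, while the
  cortical target borders CSF. With strong grey/white contrast
  (amyloid-negative late frame) the reference loses more signal than the
  target, biasing uncorrected SUVr upward; with flat contrast
  (amyloid-positive) the target loses signal to CSF while the reference is
  nearly unbiased. PVC therefore lowers SUVr in the negative case and
  raises it in the positive case — the spill-over geometry of amyloid
  imaging.
* **The T1w image is rendered analytically** on a grid with half the PET
  voxel size (1 mm vs 2 mm, mirroring the clinical resolution ratio) with
  1% Gaussian noise, rather than resampled from the label volume, so the
  higher resolution is genuine.

The four frames are defined by tissue contrasts: the early frames share a
flow-like GM:WM = 2 pattern; the late amyloid-negative frame has GM:WM =
4; the late amyloid-positive frame has GM:WM = 1.05 ("lost" contrast).
CSF activity is fixed at 5% of white matter — small but non-zero, which
keeps joint histograms non-degenerate. Expected event totals are 1e6
(early) and 2e6 (late) — desk-scale counts chosen so that the 5% bootstrap
level sits deep in the noise-limited regime while a full run stays on one
CPU; clinical frames have orders of magnitude more events, so absolute SD
values here are not comparable to clinical ones (directions and orderings
are the object of study).

## The simulator and reconstructor

The system model is parallel-beam and slice-stacked: an explicit sparse
projection matrix (Joseph-style ray sampling, half-voxel steps, bilinear
footprints, radial bin width equal to the in-plane voxel size, 56 angles =
4 x 14 subsets by default). Using one explicit matrix for both projection
and back-projection makes the pair exactly adjoint — the matched-projector
contract that guarantees MLEM's monotone likelihood. The detector PSF is
an isotropic 4 mm FWHM Gaussian applied in image space (self-adjoint, so
the matched property survives); reconstruction uses no resolution
modelling, as is standard for the clinical OSEM under study, so
reconstructed images carry the usual partial-volume blur.

Scatter is modelled as a broad radial blur (FWHM 8 bins) of the true
coincidences scaled to a 20% fraction of prompts, randoms as a spatially
uniform 10% — plausible magnitudes for brain PET, and sufficient for the
NAC/AC/QNT contrast because what matters downstream is the presence of a
structured additive background, not its microphysics.
`estimate_scatter()` re-fits this model from measured data by a tail fit
(bins whose rays miss the object, attenuation factor > 0.995), which is
how QNT reconstructions obtain their scatter estimate in the pipeline.

The 1 mm output voxel option reconstructs at 2 mm and applies
`upsample_split()` — each voxel divided into eight equal children, no
interpolation — so that high-resolution region definitions can be used
without inventing information.

## Registration engine

The in-repo engine maximises NMI (64 bins at full resolution, joint
histogram over voxels where both images are positive, no Parzen
smoothing) over a three-level pyramid (block-mean factors 4, 2, 1) with
cyclic golden-section line searches over the six parameters (1 mm scaled
to 1°), a Nelder-Mead refinement per level to handle rotation coupling,
and a deterministic grid scan over coupled rotation offsets (±1.5° to
±4.5°) at the finest level, which crosses the shallow histogram-induced
barriers that trap purely local searches. Everything is deterministic
given the inputs; the evaluation budget (2000 per level) marks results
that exhaust it as failed rather than raising, because failed
registrations are data (they are excluded from distributions and counted,
mirroring how a failed-registration point is dropped from a CoV plot).
Rotations are parameterised as intrinsic x-y-z about the image-centre
world point — rotating about the centre rather than the corner avoids
conflating rotation with large translations. External engines (SPM,
NiftyReg, ...) can be plugged in through `register_engine()` adapters; no
test depends on one.

On noiseless images the engine typically recovers ±10 mm / ±10°
displacements to about 0.02 mm / 0.02°; for a small fraction of extreme
combined displacements the rotation lands in a neighbouring histogram
optimum about 1.5° away. On low-count reconstructions the recovered
transform additionally scatters by noise-dependent amounts — that scatter
is the phenomenon under study, not an implementation defect.

## Statistical summaries

Dice and Jaccard are computed per ROI between the gold-standard and each
replicate parcellation on the 1 mm (voxel-split) grid; per-cell standard
deviations use the n−1 denominator throughout. `sd_matrix()` assembles
the per-ROI and ROI-averaged SD matrices, flags the per-frame minimum and
the cells statistically indistinguishable from it by the Brown–Forsythe
test at alpha = 0.05. Brown–Forsythe is the median-centred Levene
variant: a one-way ANOVA F on absolute deviations from group medians —
median centring is exactly what distinguishes it. ROI averages are
unweighted means over the nine analysis ROIs.

Iterative-Yang PVC uses an isotropic Gaussian PSF, default FWHM 4.5 mm
(scanner-like), five iterations with a 1e-4 relative-change stop. Each
iteration rebuilds a piecewise-constant synthetic image from current
regional means, corrects the PET by the ratio of synthetic to smoothed
synthetic, and recomputes the means. Empty regions are skipped and
recorded, not raised. SUVr propagation runs on the native 2 mm
quantitative PET (the parcellation is propagated per replicate), which
keeps per-replicate PVC affordable; the Dice analysis stays on the 1 mm
grid where overlap resolution matters.

## Seeds, determinism, resumability

Every random quantity derives from one root seed through
`derive_seed(root_seed, label)` — a rolling string hash kept below 2^31 —
so no step consumes global RNG state and any single cell can be reproduced
in isolation. Identical root seeds give byte-identical result tables;
per-cell caching (`cache_dir`) makes interrupted runs resume to the same
answer.

## Design sizes and the desk profile

`experiment_design()` defaults to the full bookkeeping design (4 frames x
3 modes x 1–3 iterations x 14 subsets, count levels 5/15/30/60%, 50
bootstrap replicates, two voxel sizes, perturbation on, one extra
reconstruction per attenuation-corrected image for attenuation-map
alignment); `enumerate_recon_param_design()` and
`enumerate_count_level_design()` count it by explicit cell enumeration —
600 resampled datasets / 1800 uncertainty images / 1200 alignment
reconstructions / 3000 total, and 800 datasets / 2400 images. The
simulation pipelines default to `reduced_design()` — two late frames, AC
mode, 2 iterations, levels 5% and 60%, 5–20 replicates on a 64³ phantom —
the problem size at which the package's own test suite demonstrates every
mechanism on a single CPU. The attenuation-map-alignment entries are
bookkeeping only: the phantom attenuation map is perfectly aligned by
construction, so these reconstructions are counted but their registration
step is a no-op.

## What passing tests do and do not show

The phantom has exact piecewise-constant tissue classes, perfectly known
attenuation, no head motion, no MR bias field or distortion, and one
anatomy. Passing tests therefore demonstrate the internal mechanisms —
bootstrap calibration, likelihood monotonicity, transform recovery, the
count-level dependence of Dice SD, the PVC variance amplification and its
amyloid-status-dependent SUVr shifts — under controlled conditions. They
do not certify absolute uncertainty magnitudes for any scanner or cohort;
on real data those depend on anatomy, tracer, counts and the registration
software used. The intended use on real data is the same pipeline with
the phantom replaced by NIfTI inputs and, optionally, external engines
behind the adapter interface.

## Known limitations

* Parallel-beam slice-stacked geometry, not cylindrical 3D PET: preserves
  the statistics of noise propagation, not scanner-specific covariances.
* Scatter is a blur model; no single-scatter simulation.
* No time-of-flight, detector gaps, dead-time dynamics or motion.
* One in-repo registration engine; conclusions about engine-to-engine
  spread require external adapters.
* The amyloid-positive late frame is modelled as globally flat GM/WM
  contrast; focal amyloid load is not simulated.
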
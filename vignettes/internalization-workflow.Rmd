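---
title: "Methods: internalization quantification for imaging flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: internalization quantification for imaging flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowintern)
```

`flowintern` quantifies the uptake and internalization of fluorescently
labelled compounds from per-cell imaging flow cytometry galleries. This
vignette is the package's own account of the underlying models, the
tunable parameters and their defaults, the synthetic-data generator that
makes the pipeline testable, and the design decisions taken where the
problem was genuinely open.

## The measurement model

Each event is a `cell_record`: a small multichannel image stack (by
convention channel 1 = brightfield, 2 = compound fluorescence, 3 =
viability dye), physical pixel size (1 µm by default), an acquisition
timestamp and a sample identity of the form `<object>_<replicate>`.

### Mask algebra

Segmentation runs on the brightfield channel, where suspension cells
appear as absorbing disks on a bright background. `object_mask()` takes
the absolute deviation from the modal background intensity, applies an
Otsu threshold, fills holes and keeps the largest 8-connected component.
The *tight* variant closes and then erodes the default mask by one pixel
(and is intersected with the default mask so that tight ⊆ default holds
unconditionally).

The cytoplasm mask is produced by `adaptive_erode()`: repeated 1-px
erosions of the object mask, stopping at the first iterate whose area is
at most a percentage coefficient of the original (70% by default, i.e.
the coefficient keeps its percent-retained meaning). Commercial
implementations of adaptive erosion follow intensity contours and are
undocumented; uniform erosion to an area target was chosen because it is
deterministic, shape-preserving, and reproduces the membrane/cytoplasm
dichotomy the analysis needs. Whether the coefficient denotes an area
percentage or an intensity-percentile contour is not specifiable from
public information; the area interpretation is adopted and documented
here. On small cells (radius 7–9 px) one erosion step changes the area by
a large increment, so the retained fraction can land well below the
target (e.g. 46% instead of 70%); the stopping rule — first iterate at or
below target — makes this deterministic and monotone in the coefficient.

The membrane ring is defined exactly as `tight AND NOT cytoplasm` (the
cytoplasm mask is intersected with the tight mask first), so membrane and
cytoplasm are disjoint and their union is the tight object for every
cell — a set identity the test suite asserts on whole galleries, not a
statistical tendency. A nucleus mask, when a nuclear channel is supplied,
is the object mask on that channel eroded 3 px (configurable), clipped to
the cell object.

One convention is used throughout: 8-connected components and a 3×3 box
structuring element. A consequence worth knowing: box erosion shrinks a
disk by n px along the axes but up to n·√2 px along diagonals, so n
erosions of a radius-r disk sit between the rasterized disks of radius
r − n√2 and r − n.

### Per-cell features

* **Intensity**: background (modal intensity outside the object mask,
  256-bin histogram mode — robust to puncta) is subtracted, negatives are
  clipped, then sum/mean/max over the mask.
* **Morphometrics**: area (pixel count × pixel size²); perimeter (traced
  contour length); circularity = mean/SD of boundary-pixel distances to
  the centroid (capped at 100 for degenerate lattice circles);
  aspect ratio = minor/major axis of the second-moment ellipse. The exact
  formulas used by commercial software are unpublished; these are
  documented stand-ins with the same ordering behaviour (round cells
  score high circularity and aspect ratio ≈ 1).
* **Focus (gradient RMS)**: RMS of the central-difference gradient
  magnitude over the mask, divided by the mean in-mask intensity and
  scaled ×100. Note that central differences sample pixels two apart, so
  a 1-px checkerboard is invisible to this metric; the roughest visible
  pattern is a 2-px checkerboard.
* **GLCM entropy**: in-mask intensities are quantized to 256 levels by
  linear min–max scaling (making the statistic invariant under affine
  intensity rescaling — asserted by test), co-occurrences are accumulated
  for all pixel pairs with both endpoints in the mask at a 1-px offset
  (granularity 1 µm at 1 µm/px), over the four standard directions,
  symmetrized, and the Shannon entropy of the normalized matrix is
  reported in bits. A constant region has exactly one co-occurrence cell
  and entropy exactly 0. The implementation is verified against an
  independently written brute-force pair enumeration to 1e-9 on hundreds
  of random images.
* **Internalization coefficient**: IC = log10 of the ratio of *mean*
  background-subtracted intensity in the cytoplasm mask to the mean over
  the object mask, clamped to [−6, 6]. Means, not sums: with sums a
  subset mask could never exceed the whole cell and the "IC > 0 ⇒
  internalized" gate could never fire. A cell with no whole-cell signal
  is unscorable (missing), and a cytoplasm mean of zero clamps to −6.
* **Bright-detail similarity**: white top-hat (disk radius 3 px) of each
  channel keeps only small bright spots; their Pearson correlation over
  the mask, clamped below at 0, gives a colocalization score in [0, 1].
  A "log-transformed" variant of this score is sometimes described, but
  no transform maps correlations in [0, 1] to [0, 1] consistently with
  the published description, so the clamped raw correlation is reported.
* **1D profile colocalization**: both channels sampled along a line
  segment (unit spacing, bilinear interpolation); the signed Pearson r is
  returned — negative when one signal sits inside the ring traced by the
  other, positive when both run along the membrane.

### The gating cascade

Fixed order: focus → time → singlets → viable → uptake → internalized.
Defaults, with units and rationale:

| gate | parameter | default | convention |
|---|---|---|---|
| focus | min gradient RMS | 40 | inclusive ≥ |
| time | min timestamp | 20 s | inclusive ≥ |
| singlets | area range | [50, 300] µm² | inclusive |
| singlets | min aspect ratio | 0.6 | inclusive ≥ |
| viable | max viability total | 1×10⁴ a.u. | **strict <** |
| uptake | min compound total | control mean + 3·SD (`"auto"`) | inclusive ≥ |
| internalized | min IC | 0 | **strict >** |

The two strict inequalities follow the workflow's wording for live cells
("intensity level < 1×10⁴") and internalized cells ("coefficient > 0");
all other bounds are inclusive, decided once and applied everywhere. The
time gate exists to exclude carryover from the previous sample; "20–30 s"
is read as *exclude events before t\_min = 20 s* (configurable). The focus
and singlet thresholds have no published values; the defaults are
calibrated against the synthetic generator (sharp cells score ≈ 44–53,
σ = 3-blurred cells ≈ 11, so 40 separates them; doublets score aspect
ratio ≈ 0.5, singlets ≈ 1) and must be re-tuned for real instrument data.

Per-sample summaries report viable-single % of all events, uptake % of
viable singles, internalized % of uptake-positive cells, and the median
cytoplasmic entropy and median IC of uptake-positive cells.

### Spillover compensation

Spillover is estimated from single-stain controls as S[i, j] = median
over positive events (primary total above background + 3 SD) of the
channel-j/channel-i total ratio, with unit diagonal. A median-ratio
estimator was preferred over a regression slope because it is robust to
the generator's noise structure and to a handful of dim events.
Compensation right-multiplies observed per-cell totals by S⁻¹; data mixed
exactly by S are recovered to machine precision. Compensation acts on
scalar per-cell totals, not per pixel — sufficient for gating, which only
consumes totals.

### Statistics

Reports are parsed by locating the header line containing `File` (so
preamble lines are tolerated) and splitting each file stem on its *last*
underscore — object names may themselves contain underscores
(`PS_LNA_mix_2.daf` → object `PS_LNA_mix`, replicate 2).

Between objects at one timepoint: one-way ANOVA by direct sum-of-squares
decomposition, F = MSB/MSW, ω² = (SSB − (k−1)·MSW)/(SST + MSW). The 95%
CI for ω² inverts the noncentral-F distribution in the noncentrality λ
and maps the bounds through ω² = λ/(λ + N); no method for this CI is
prescribed anywhere, and this is the standard pivot construction. Tukey
HSD uses the studentized range with pooled MSW and Tukey–Kramer standard
errors for unequal n; Cohen's d uses the pair's pooled SD.

Within one object over time: a one-way within-subject decomposition
(SS_subject + SS_time + SS_error = SS_total, asserted to 1e-9), F =
MS_time/MS_error, GES = SS_time/(SS_time + SS_subject + SS_error). A zero
error stratum yields an infinite F, reported as `Inf` with a flag rather
than silently capped. The GES 95% CI is a seeded percentile bootstrap
over subjects (2000 resamples by default) — again no prescribed method
exists, and the bootstrap makes no distributional assumption. No
sphericity correction is applied by default (none is prescribed);
the decomposition is the uncorrected one. Paired t-tests between
timepoints use complete pairs, Cohen's dz = mean(diff)/SD(diff), and
pairs with zero difference SD are logged as zero-variance with no
p-value. The implementation computes all of these directly so that base
R's `aov()`/`TukeyHSD()` can serve as genuinely independent oracles in
the test suite; agreement is asserted to 1e-6 on randomized designs.

BH families: all Tukey pairs within one (parameter, timepoint) form one
family; all time pairs within one (parameter, object) form another.
Significance is declared at adjusted p < 0.05. Exclusion rules mirror the
replicate minima a reliable comparative analysis needs: at least two
replicates per group, at least two complete replicates across all
timepoints, nonzero variance; excluded units stay in the descriptive
statistics and are listed with reasons. Since no xlsx writer is among the
package's dependencies, the four result sections (descriptives, ANOVA &
Tukey, RM-ANOVA & t-tests, exclusions) are exported as CSV files plus a
raw CSV mirror, written at full precision and byte-stable across reruns.

## The synthetic generator

`synth_config()`/`generate_gallery()` emulate the statistical and optical
structure the analysis relies on, not instrument physics:

* Round suspension cells (MT-4-like lymphoblasts): absorbing disks,
  radius 7–9 px at 1 µm/px (14–18 µm diameter), with mild internal
  texture so brightfield segmentation is well-posed. The radius range was
  chosen once so that singlet areas (149–253 µm²) sit inside the default
  singlet area gate.
* Compound channel: a membrane ring of width 2 px carries
  (1 − f)·total_signal and the interior carries f·total_signal, either as
  a flat field with multiplicative speckle (diffuse) or as a handful of
  Gaussian foci (punctate) — realizing the high- vs low-entropy contrast.
  Pre-noise channel sums are renormalized, so signal is conserved
  exactly.
* Viability channel: 5×10⁴ total for dead cells, 1×10³ for live ones,
  straddling the 1×10⁴ gate.
* Doublets: two overlapping disks with centers 1.6 radii apart. At this
  separation the union's second-moment aspect ratio is ≈ 0.5, safely
  below the 0.6 singlet gate; at 1.2 radii (a value one might guess
  first) the measured aspect ratio is 0.605 — *above* the gate — so 1.6
  was fixed by direct measurement before any downstream test existed.
* Defocus: Gaussian blur with σ = 3 px; noise: additive Gaussian
  (σ = 2 a.u.) plus a flat fluorescence background (10 a.u.), clipped at
  zero.
* Timestamps: cumulative exponential gaps at 5 events/s, so a 500-event
  gallery spans ≈ 100 s and the 20 s time gate removes about a fifth.

**Class allocation.** Gallery-level fractions (dead, doublet, defocused,
internalized-type) are realized by exact-count allocation — `round(f·n)`
events of each class, positions drawn by random permutation — rather than
independent Bernoulli draws. The population composition is a *condition*
of a simulated experiment, not a quantity under study; fixing it removes
binomial jitter from every recovery experiment while leaving within-class
randomness intact. At the gallery level `internalized_fraction` is the
fraction of *cells* of the internalized type (per-cell signal fraction
1), mirroring the internalized/non-internalized dichotomy the cascade
recovers; `generate_cell()` retains the continuous per-cell split for
single-cell experiments. All randomness flows from one seed, with
per-cell substreams derived by counter, so identical configurations give
bit-identical galleries.

**What the generator does not emulate** — and hence what passing tests do
and do not show: realistic optics (no PSF model beyond Gaussian blur),
spectral emission physics, autofluorescence, cell-cycle or morphology
heterogeneity beyond radius jitter, touching-cell segmentation (doublets
are gated out, never split), and camera noise models (no Poisson shot
noise). Recovery of a 70% internalized population to within a point on
synthetic data demonstrates that the mask algebra, feature definitions
and gate logic compose correctly; it does not validate the focus or
singlet thresholds for any real instrument.

## Numerical choices and degenerate inputs

* Erosion/closing use a 3×3 box kernel (8-connected) everywhere.
* `adaptive_erode` at coefficient 100 is the identity; a mask that would
  be emptied returns its last nonempty iterate (a 1-px mask is returned
  unchanged).
* Blank images (zero dynamic range) raise an error at segmentation;
  unsegmentable events are dropped from feature tables rather than
  aborting a gallery run.
* GLCM entropy with no valid pixel pair is missing, not 0; a constant
  region is exactly 0.
* IC is clamped to [−6, 6]; zero whole-cell signal gives a missing value.
* Tie-breaking at gate boundaries is fixed (see the table above) and
  asserted by tests at the exact boundary values.
* Report and CSV numerics are written with 17 significant digits so
  write→parse round trips reproduce doubles exactly.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at these sizes, chosen to exercise every code path at desk scale:
200 random 32×32 images for the entropy oracle, 500-cell galleries for
mask-algebra and end-to-end recovery, 200-cell galleries per arm for the
IC sign experiment, 100 matched pairs for the entropy ordering, 40-event
single-stain controls, and 20 randomized small designs for the statistics
oracles.

## Known limitations

* The area-fraction reading of adaptive erosion, and the circularity and
  focus formulas, are documented approximations of undocumented
  commercial counterparts; numerical equivalence with those tools is not
  claimed.
* Rectangular gates only; no polygon gating, no interactive gate drawing.
* Compensation handles the two-dye case well; full unmixing of many
  overlapping dyes and autofluorescence modelling are out of scope.
* The nucleus-internalization analysis is available through the feature
  layer (IC against the nucleus mask) but has no dedicated gate.
* Two-way or mixed statistical designs are not implemented; the
  statistics layer covers the between-object and within-object one-way
  analyses described above.
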
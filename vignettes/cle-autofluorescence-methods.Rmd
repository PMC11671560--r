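---
title: "Label-free CLE autofluorescence analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free CLE autofluorescence analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cleaf)
```

## The problem

Clinical confocal laser endomicroscopy (CLE) can image endogenous tissue
fluorescence — autofluorescence from NAD(P)H, flavins, lipofuscin, elastin —
without any applied dye, at cellular resolution and intraoperatively. Frames
are single-channel, 16-bit, 1920 × 1080 pixels covering a 267 × 475 µm field
of view (FOV), acquired with either a green bandpass (BP) or longpass (LP)
emission filter. Such label-free recordings of brain tissue show a small
repertoire of recurring structures: punctuate granules (1–3 µm), cells with
fluorescent cytoplasm (small < 25 µm, large ≥ 25 µm), curvilinear fibers,
weakly and homogeneously fluorescent round structures (10–60 µm,
psammoma-body-like), and diffuse autofluorescence filling much of the FOV,
often with negative-contrast silhouettes.

`cleaf` turns the visual scoring of such frames into a tested, reproducible
pipeline: (i) a synthetic frame generator with ground truth, (ii) automated
quality-control (QC) exclusion of uninterpretable frames, (iii) line-profile
signal-to-noise (SNR) estimation with a paired Wilcoxon comparison of the
two emission filters, (iv) detection and classification of nine
autofluorescence features per frame, and (v) per-case abundance summaries
rendered as Chernoff-face glyphs. Because clinical CLE images of patients
are not openly distributable, the generator is a first-class module: it
defines the study conditions under which every quantitative claim of this
package is tested.

## Frame geometry

The device reports a 267 × 475 µm FOV on 1920 × 1080 pixels. The two axis
ratios agree to better than 0.1 % under a single square pixel pitch of
475/1920 ≈ 0.2474 µm, which the package adopts (`cle_geometry()`); the
vertical extent then comes out at 267.2 µm. Coordinates use a row-major,
pixel-center convention; object positions are stored in micrometers and
converted through the pixel pitch.

## Image formation in the synthetic generator

A scene (`scene_spec()`) is rendered (`render_scene()`) as

1. a flat background: `bp_background` gray units for BP frames, plus
   `lp_background_offset` for LP frames (the longpass filter admits more
   background light);
2. an optional diffuse component: a plateau of `diffuse_level` gray units
   modulated ±15 % by a smooth random field (coarse-grid noise, Gaussian
   blurred, bilinearly upsampled) minus a few soft-edged negative-contrast
   disks;
3. additively stamped objects — Gaussian spots whose FWHM equals the
   annotated diameter; cells as soft-edged disks (half-amplitude crossing
   exactly at the annotated radius) with a darker nucleus and granular
   multiplicative cytoplasm texture; fibers as smoothed random-walk
   polylines with Gaussian cross-section; round structures as soft-edged
   homogeneous disks at a weaker amplitude; optional dark curvilinear
   vessels;
4. detector noise in one pass: gain-scaled Poisson shot noise plus Gaussian
   read noise, then quantization to the 16-bit range.

Object amplitudes are specified in units of the BP background noise
standard deviation (`object_contrast`, default 8), so detectability is a
controlled quantity. Amplitudes are identical in the two frames of a
BP/LP pair (`render_pair()`); the pair shares its geometry stream and
differs only in background level and in independent noise realizations.

**Noise defaults.** Clinical label-free CLE frames are dominated by
detector noise at the high gain needed for weak autofluorescence. The
defaults therefore put most of the noise in the Gaussian read term
(`read_sigma = 30`) and little in the shot term (`poisson_scale = 0.05`,
i.e. shot variance = 0.05 × intensity): at the default background of 500
the background standard deviation is √(25 + 900) ≈ 30.4, only ~2 % higher
in LP frames despite the 200-unit background offset. This is also what
makes the paired-filter comparison a genuine null: with matched signal
amplitudes, an offset that raised the noise materially would produce a
systematic SNR difference that a 50-pair Wilcoxon test would detect.
Where the Poisson mean per pixel exceeds 1000 the sampler uses the
Gaussian limit of the Poisson folded into the read noise (skewness
< 0.04 at that mean); the exact Poisson path is used below it, e.g. in
the shot-noise calibration checks.

**Autobrightness.** The device rescales display brightness automatically,
but its algorithm is unpublished. The package ships the emulation as a
separate step (`emulate_autobrightness()`, default target 5 % of the
dynamic range) rather than applying it inside `render_scene()`: raw
renders keep the physical noise model interpretable (an object-free frame
has mean `bp_background` and variance `poisson_scale × mean + read_sigma²`),
which the test suite verifies directly.

**Reproducibility.** One root seed drives everything through labeled
substreams (a hash of seed and stream name), so each object class, the
diffuse field, and each filter's noise consume independent streams:
adding one object class never perturbs another's draws, and BP/LP noise
is independent while geometry is shared. Normal deviates use the
Kinderman–Ramage generator (several times faster than inversion on 2-Mpx
fields, equally deterministic). Fixed seed implies bit-identical frames.

**Placement.** Objects are placed by rejection sampling with
class-appropriate keep-out distances (cells never overlap other disk-like
objects; spots keep four radii apart so the blob detector's resolution is
not the limiting factor; fibers may cross cells but not round structures).
A thousand failed retries raise a packing error, as does a requested
footprint above ~75 % of the FOV. Objects are placed fully inside the
frame; clipped objects are not emulated.

**Artifacts.** Three acquisition-artifact classes can be injected
(`inject_artifact()`): *blank* (background plus noise only — no
discernible signal), *motion* (convolution with a line kernel of given
length at a random orientation plus fresh read noise), and *duplicate* (a
sub-pixel-to-small shift of an earlier frame with fresh noise) — the three
reasons for which in situ frames are excluded from scoring.

## Quality control

`qc_pipeline()` applies three flags with total precedence
no-signal → motion → duplicate:

* **No discernible signal** — fraction of pixels above median +
  `k_sigma` × 1.4826 MAD below `min_frac` (defaults 4 and 10⁻⁴). Robust
  statistics, because bright objects bias mean and standard deviation. A
  constant frame is blank by definition.
* **Motion** — gradient-energy anisotropy: the ratio of structure-tensor
  eigenvalues over the strongest-gradient pixels of a smoothed,
  downsampled copy. Clean synthetic frames score near 1 (observed ≤ 1.8),
  frames smeared over 50 px score ≥ 2.9; the default threshold 2.3 sits
  between the two calibration bands.
* **Duplicate** — maximum normalized cross-correlation against earlier
  kept frames of the same case, on 8×-downsampled, smoothed, standardized
  thumbnails over shifts up to 10 % of the FOV. Duplicated fields of view
  score ≥ 0.99 even with fresh noise (the smoothing removes the
  uncorrelated pixel noise); independent fields score ≈ 0.1; the default
  threshold is 0.95. Comparing only within a case, in acquisition order,
  makes the duplicate graph acyclic by construction.

Cohort tallies report integer percentages rounded half away from zero and
reconciled to a sum of 100 by largest remainder. The same rounding
reproduces the printed arithmetic of an in situ series of 338 frames with
counts 53/141/73: 16 %, 42 %, 22 %, with 71 frames left as similar-FOV
exclusions. Blood contamination and out-of-focus areas have no
operational criteria here and are listed as unsupported categories.

The quantitative flags are surrogates calibrated on the synthetic suite
only; no claim is made that they reproduce a human rater's judgment on
clinical frames.

## Line-profile SNR and the filter comparison

Gray values are sampled along a line crossing a fluorescent object at
unit-pixel spacing with bilinear interpolation (`extract_profile()`), and
each sample is allocated to *signal* or *background*
(`allocate_profile()`). The original allocation was manual; the automatic
method is a one-dimensional Otsu threshold (exhaustive maximization of
between-class variance), with manual labels remaining first-class. Then
(`compute_snr()`)

SNR = Δµ / σ,

the difference of mean gray values (signal − background) over the standard
deviation of the background. The background s.d. uses the sample (n − 1)
form by default — background segments are short, so the unbiased form is
safer — with a flag for the population form; nothing in the statistic's
definition fixes the choice.

`compare_filters()` performs the two-sided Wilcoxon signed-rank test on
paired BP − LP differences. Zero differences are dropped (signed-rank
convention). For up to 25 effective pairs the null tail is exact,
computed from the generating function of the signed-rank sum over doubled
(possibly tied, average) ranks — identical to full sign enumeration but
polynomial in n; above 25 a normal approximation with tie and continuity
correction is used. Two-sided p doubles the smaller tail, capped at 1.
The test suite checks the exact path against brute-force 2ⁿ enumeration
(including ties) and, on tie-free inputs, against `stats::wilcox.test`.

The paired-filter study (`snr_pair_study()`, `paired_null_study()`)
renders pairs holding one 15-µm cell at contrast 5, profiles it over
45 µm, and compares filters per cohort of 50 pairs across 20 replicate
cohorts. Under matched amplitudes and read-dominated noise the expected
result is a null: median SNR difference within ±0.3 of zero and p > 0.05
in ≥ 90 % of cohorts. Note the irreducible Monte-Carlo character of that
last figure: even under a perfect null, p > 0.05 holds per cohort with
probability ~0.95, so ≥ 18 of 20 cohorts is itself a stochastic event
with ~90 % probability.

## Feature detection

The nine features scored per frame, with their count thresholds:

| # | feature | rule |
|---|---------|------|
| 1 | sparse punctuate | 1–3 µm signals, 1–49 per FOV |
| 2 | dense punctuate | 1–3 µm signals, ≥ 50 per FOV |
| 3 | sparse small cells | fluorescent cytoplasm, < 25 µm, 1–4 per FOV |
| 4 | dense small cells | ≥ 5 per FOV, < 25 µm |
| 5 | sparse large cells | ≥ 25 µm, 1–4 per FOV |
| 6 | dense large cells | ≥ 25 µm, ≥ 5 per FOV |
| 7 | diffuse autofluorescence | coverage ≥ 50 % of FOV |
| 8 | fibers | ≥ 1 fiber |
| 9 | round structures | ≥ 1 structure, 10–60 µm |

Scoring in the original workflow was visual; this package substitutes
explicit detectors and keeps the thresholds as a pure classification layer
(`classify_features()`), tested exhaustively at the 49/50, 4/5 and
24.9/25 µm boundaries. A sparse flag requires at least one detection — an
empty frame shows a feature as absent, not sparse (reading "< 50" as
including zero would be clearly unintended). The 25 µm boundary assigns to
the large class. Counts are raw per-frame counts without edge correction.
Detectors:

* **Spots** — scale-normalized Laplacian-of-Gaussian over diameters
  1–3 µm, composed with a broad high-pass (σ = 12 px) so diffuse
  autofluorescence and cell bodies stay out of the blob band. Responses
  standardized per scale by robust spread; threshold 10 noise units with
  an absolute floor (3 gray units) guarding noiseless frames; greedy
  distance-based non-maximum suppression; sub-pixel quadratic peak
  refinement; estimated diameters outside 1–3 µm (± 1 px) discarded.
* **Cells** — threshold on the σ = 2 px smoothed frame at 12 smoothed-noise
  units above background with a quantile guard (the 95th percentile plus
  margin) that lifts the threshold above any diffuse plateau without
  tracking the cells themselves; hole filling; connected components;
  equivalent diameter from area. Components ≤ 3 µm belong to the punctuate
  class; elongated components (aspect > 4) are left to the fiber detector;
  homogeneous interiors (coefficient of variation ≤ 0.16) are
  round-structure candidates, cells being defined by granular cytoplasm.
* **Fibers** — Hessian ridge filter at three scales on a 2×-downsampled
  copy (widths ~1–4 µm), blob-suppressed via the eigenvalue ratio,
  thresholded at 20 noise units (calibration: real fibers score ≥ 80,
  rim/wrap artifacts ≤ 11), thinned (Zhang–Suen), and measured as the
  longest geodesic path of each skeleton component via its graph. A fiber
  must be an open curve (closed cell rims have no endpoints), ≥ 25 µm
  long, ≤ 5 µm wide, with length/width ≥ 5; spurs below 10 µm never
  affect the longest path.
* **Round structures** — LoG at radii 5–30 µm on a 4×-downsampled copy
  with containment-aware suppression (larger disks absorb the small-scale
  edge-ring maxima inside them); candidates kept when the interior is
  homogeneous (CV ≤ 0.16) and the mean intensity sits between the noise
  floor and cell-level brightness; diameters outside 10–60 µm discarded.
* **Diffuse** — normalized-convolution smoothing (σ = 12 px on an
  8×-downsampled grid) of the frame with all detected objects masked
  (generously dilated); coverage is the fraction of the FOV where the
  smoothed residual exceeds its 5th-percentile floor by a threshold set
  well above the propagated pixel noise (max of 6 smoothed-noise units
  and 8 % of the pixel noise s.d.); the flag fires at 50 % coverage.

`detect_features()` runs all four detectors plus the diffuse criterion and
resolves cross-class conflicts so that no detection is counted twice:
punctuate detections on fiber skeletons or inside cells/round structures
are suppressed, merged spot pairs masquerading as tiny cells are dropped,
ridge arcs along round-structure rims and granule chains threading through
cells are not fibers, and homogeneous patches against a larger cell are
not round structures. Frame borders as wide as the largest filter support
are excluded in the frequency-domain detectors (circular FFT filtering
wraps content across borders).

All thresholds live in `detect_config()` and `qc_config()` — configuration
data with documented defaults, each calibrated once on the synthetic suite
at the default contrast — not constants in code.

## Cohort aggregation and glyphs

`aggregate_case()` computes, per case, the percentage of analyzable frames
in which each feature was detected (QC-excluded frames never enter).
`cohort_report()` writes bar-chart data, a per-tumor-type table of median
case percentages, and a Chernoff-face grid. The feature-to-face mapping is
fixed: face size ← sparse punctuate; forehead/jaw relative arc ← diffuse;
forehead shape ← fibers; jaw shape ← dense punctuate; eye angle ← round
structures; pupil direction ← sparse small cells; nose length ← dense
large cells; mouth shape ← dense small cells; mouth arc ← sparse large
cells. Parameters are percentages divided by 100, componentwise and
without winsorizing; all unmapped facial parameters sit at 0.5 (the
original renderer's default value is unknown; 0.5 is this package's
convention). The face geometry itself — elliptical face, Bézier forehead
and jaw, slanted eyes with displaced pupils, vertical nose, curved
mouth — is an original construction documented in `R/glyph.R`; rendering
is plain SVG text, byte-deterministic, and every parameter moves some
coordinate. On cohorts built from cell-rich "non-tumor-like" scenes versus
cell-poor "tumor-like" scenes, the mouth, nose and pupil parameters (all
cell-derived) separate the groups by construction — a parameter-level
statement, not a perceptual claim.

## Scene archetypes

`random_scene_spec()` samples five archetypes patterned on the tissue
phenotypes seen in label-free CLE of brain tumors and non-tumor brain:
glioblastoma-like (dense punctuate, 60–120 spots, occasional diffuse),
meningioma-like (sparse punctuate with fibers, round structures and
frequent diffuse signal), metastasis-like and adenoma-like (sparse
punctuate with some cells), and non-tumor-like (dense small cells, 5–12
per frame, plus large cells). Sparse and dense regimes are sampled away
from the 50-signal knife edge (≤ 40 vs ≥ 60), mirroring how loosely
distributed and densely packed punctuate patterns present as visually
distinct phenotypes; cell counts do straddle their 5-per-FOV threshold,
so those flags genuinely exercise count accuracy. Diffuse scenes use a
level of 90 gray units ≈ 3 × the background noise s.d.

## What the synthetic studies do and do not show

The generator emulates geometry, amplitude classes and detector-dominated
noise, and it is the sole ground-truth source for detector validation.
It does not model the fiber-bundle optics (honeycomb sampling), spectral
properties, autobrightness dynamics, blood contamination, out-of-focus
blur, or clipped objects; real backgrounds' intensity distribution is
unknown, and the defaults are configurable rather than claimed faithful.
Passing the recovery criteria therefore shows that the detectors recover
the planted morphology classes under the stated noise model — not that
they match human scoring of clinical frames.

## Problem sizes and numerical choices

The test suite runs the studies at: 20 cohorts × 50 BP/LP pairs
(paired-filter null), 100 randomized scenes (flag recovery ≥ 85 % overall,
≥ 95 % punctuate), 5 × 30 spots at contrast 8 (recall/precision ≥ 0.9),
300 labeled frames (QC sensitivity/specificity ≥ 0.95), 500 simulated
profiles (SNR consistency), and 200 enumeration checks (exact Wilcoxon).
`scripts/acceptance.R` recomputes the same quantities at 60 recovery
scenes and 150 QC frames, sizes chosen as representative samples of the
same conditions. FFT filtering is circular with cached transfer
functions; robust scale is 1.4826 × MAD throughout; percentages round
half away from zero; degenerate inputs (constant profiles, zero
backgrounds, empty frames) raise typed errors rather than propagating
NaN.

## Known limitations

Detector thresholds are calibrated at the default contrast of 8 background
s.d.; substantially dimmer objects need recalibrated configs. Touching
cells are not split (no watershed; the generator does not overlap cells).
Fiber width is overestimated by the mask support (~2× for thin fibers);
length, which feeds the classification, is accurate to within the stated
20 %. The duplicate flag compares whole fields of view and will not catch
partial overlaps below the correlation threshold. The in situ category
arithmetic is self-contained, but the QC flags themselves are synthetic
calibrations, not reproductions of a rater.
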
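---
title: "Automated HER2/CEP17 quantification from brightfield SISH images"
author: "SISHscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated HER2/CEP17 quantification from brightfield SISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SISHscore)
```

## The quantification problem

HER2 gene amplification guides targeted therapy in breast cancer. In
silver in situ hybridization (SISH), a brightfield technique, each HER2
gene copy appears as a black dot and each chromosome-17 centromere
(CEP17) as a red dot inside a counterstained nucleus. The clinical
quantity is the ratio of total HER2 to total CEP17 signals over a
representative set of tumor nuclei; under ASCO/CAP-style criteria a
region scores Positive when that ratio reaches 2.0. Manual enumeration
is slow and subject to inter-observer variability; this package
automates it for regions of interest (ROIs) extracted from whole-slide
images at high resolution (the defaults assume 0.13 µm/pixel, a 40x
scan — at coarser resolutions the two probe dot classes become hard to
resolve).

The pipeline is deliberately modular, and each stage is exposed as an
ordinary function so that any stage can be replaced or audited:

1. **Preprocessing** — per-channel intensity normalization and gamma
   adjustment (`normalizeValues()`, `gammaAdjust()`, `normalizeRoi()`).
2. **Signal detection** — background removal, HSV color thresholding,
   8-connected component grouping, physical size filtering, faint-signal
   removal and area-based cluster decomposition (`detectSpots()`,
   `removeFaint()`).
3. **Nucleus segmentation** — a pluggable backend contract
   (`SegmentationBackend`); the default is a classical
   stain-threshold / distance-transform / watershed segmenter
   (`watershedBackend()`), and `labelBackend()` ingests label maps
   produced by external instance segmenters such as star-convex-polygon
   deep networks.
4. **Qualification** — exclusion of border-truncated nuclei, of nuclei
   overlapping another instance by more than 50 % of their own area, and
   of nuclei with fewer than two CEP17 signals, with a single-CEP17
   fallback (`qualifyNuclei()`).
5. **Scoring** — ranking by the differentiation value
   (HER2 − CEP17 count), selection of at least 20 nuclei, the
   ratio/copy-number arithmetic and the status call (`scoreNuclei()`,
   `classifyStatus()`).
6. **Evaluation** — Bland-Altman agreement against reference scores,
   a paired t-test and misclassification tabulation
   (`blandAltman()`, `compareMethods()`).

## Preprocessing choices

`normalizeValues()` implements plain min-max rescaling: each element is
mapped by `(x - min) / (max - min) * (upper - lower) + lower`. Two
interpretations of the bounds are supported because both are useful and
both circulate in practice. In `value_range` mode (the default) the
bounds are the target output range; the pipeline uses `[0, 1]`, which
puts every channel on the scale the HSV thresholds are defined on. In
`percentile` mode the bounds are percentile ranks — e.g. 1 and 99.8 —
whose input quantiles replace the minimum and maximum before mapping to
`[0, 1]` with clipping. Percentile clipping is the robust variant: a
handful of specular or dust pixels cannot compress the histogram of
interest. Constant inputs (blank tiles) map to the lower bound with a
warning instead of failing, so batch runs survive empty ROIs.

Channels are always normalized independently and never mixed; mixing
would shift hue and saturation and with them the color identity of the
two probes.

Gamma adjustment, `clip(gain * x^gamma, 0, 1)`, lifts mid-tones before
thresholding. Three operating points are supported — `(0.9, 1)`,
`(0.5, 1)` and `(0.5, 2)` as (exponent, gain) — and `(0.5, 1)` is the
default as the middle configuration; the detection thresholds below were
chosen to be compatible with all three.

## Signal detection

No universally printed thresholds exist for SISH dot colors, so the
defaults are stated explicitly and every one is a configuration key
(`signals.*`):

| parameter | default | meaning |
|---|---|---|
| `whiteness_min` | 0.90 | pixels whose minimum channel exceeds this are background |
| `her2_value_max` | 0.35 | HER2 candidates are dark ... |
| `her2_saturation_max` | 0.45 | ... and chromatically neutral |
| `cep17_hue_halfwidth_deg` | 25 | CEP17 candidates lie within 25° of pure red |
| `cep17_saturation_min` | 0.30 | ... with real chroma |
| `cep17_value_min/max` | 0.2 / 0.9 | ... neither black nor blown out |
| `min/max_spot_diameter_um` | 0.4 / 2.5 | physical size bounds, converted to pixel areas |
| `faint_contrast_min` | 0.15 | minimum contrast after detection |

Candidate pixels are grouped with 8-connectivity. Components outside
the physical size bounds are discarded; the bounds are expressed in
micrometres and converted through the ROI resolution so they transfer
across scanners. Spot contrast is mean darkness (`1 − value`) for HER2
and mean `saturation × redness` for CEP17, where redness falls linearly
from 1 at hue 0° to 0 at 180°.

HER2 probes cluster. Whether a cluster should count once or as its
multiplicity is genuinely ambiguous, so both behaviors are kept behind
`cluster_split`. When enabled, a component's signal count is
`max(1, round(area / median singleton area))`; the median singleton
area is the lower-value median over surviving components no larger than
twice the smallest surviving component. This mirrors how a pathologist
counts a large fused cluster as several signals and is directly testable
with planted cluster areas. The reference area is taken from the
observed smallest components rather than the configured minimum-area
bound because typical dots sit several times above that bound.

## Nucleus segmentation and qualification

The default backend thresholds nuclear stain (hue window 160–340°,
saturation ≥ 0.05, non-background, not a probe-dot candidate), unions
the probe-dot pixels back in (dots sit inside nuclei; leaving them out
would punch holes), fills residual holes, and applies a watershed on the
distance transform with a minimum seed separation of 0.5 µm. Instances
below 20 µm² are treated as debris. Touching nuclei separate cleanly
down to center distances of about 1.2 nucleus radii; heavily fused pairs
(beyond what the watershed can resolve) are instead caught by the
qualification rules.

Qualification applies three exclusions in a fixed order, and nothing
else: border contact (truncated nuclei carry incomplete counts), more
than 50 % own-area overlap with another instance (only reachable for
polygon backends whose instances may overlap — rasterized label maps
pass trivially), and fewer than two CEP17 signals. Overlap fractions are
computed once on the full instance set; when two instances each exceed
the bound against the other, both are removed, which makes the outcome
independent of instance ordering. In strongly amplified tissue no
nucleus may show two CEP17 signals; the fallback then admits single-CEP17
nuclei and flags the score (`fallbackUsed`), mirroring manual practice.

Spots are assigned to the nucleus covering their rounded centroid; a
spot straddling a boundary therefore contributes to exactly one nucleus,
and the assignment conserves total signal mass.

## Scoring

Qualified nuclei are ranked by descending differentiation value
(HER2 − CEP17), with ties broken by higher HER2 count and then lower
label, a deterministic total order. The first 20 nuclei are selected;
if the mean HER2 copies per nucleus falls in the recount band `[4, 6)` —
the band that clinically mandates counting further nuclei — and more
ranked nuclei exist, the next 20 are added and totals recomputed over at
least 40. Regions with fewer than 20 qualified nuclei are scored anyway
and flagged `lowConfidence`: refusing to score would discard exactly the
sparse regions where an automated count is most useful, and several
regions in the bundled reference table qualify fewer than 20 nuclei.

The reported ratio is rounded to two decimals half away from zero
(matching clinical report formatting); classification always uses the
unrounded value. Three calling modes exist. The default `binary_ratio`
(Positive at ratio ≥ 2.0) matches how the bundled reference comparison
was scored, where regions are labelled only amplified or non-amplified.
`three_way_ratio` adds an Equivocal band over `[1.8, 2.0]`: published
three-band criteria in this field print overlapping bands (Equivocal up
to 2.2 while Positive starts above 2.0), which cannot be implemented
as printed; the package resolves the overlap in favor of the 2.0
boundary used everywhere else. `asco_full` adds the copy-number bands
(≥ 6 Positive, `[4, 6)` Equivocal) for sub-cutoff ratios.

## The synthetic scene generator

Real annotated SISH data cannot ship with a package, so `simulateRoi()`
renders ROIs with exhaustive ground truth: a light eosin-toned
background, bluish elliptical nuclei (radius ~N(3.5, 0.4) µm, truncated
to `[2.9, 5.5]` so every rendered nucleus clears the 20 µm² debris
threshold), black HER2 and red CEP17 disks with radii 0.3–0.37 µm,
optional merged clusters (k disks at 1.9 r spacing, rendered at the
median dot radius so area-ratio decomposition is unbiased), faint dots,
border-clipped nuclei, deliberately overlapping nucleus pairs and
Gaussian pixel noise. Placement is rejection-sampled so only the
planted pairs overlap; dot entities keep enough separation to form
distinct connected components. Identical spec and seed give bit-identical
output.

Four presets encode the study conditions exercised by the tests:
`normal` (25 nuclei, 2 HER2 / 2 CEP17 each), `amplified` (30 nuclei,
6/2), `equivocal` (45 nuclei, 5/3 — copies per nucleus 5.0, inside the
recount band) and `high-positivity` (25 nuclei, 8/1, forcing the
fallback).

What the generator does *not* emulate bounds what passing tests show
about real data: there is no out-of-focus blur, no scanner color
variation, no stain inhomogeneity, no touching dot pairs across nucleus
boundaries, and nuclei are perfect ellipses. Recovery of planted truth
therefore validates the bookkeeping — detection, assignment,
qualification, and scoring arithmetic — not the color thresholds'
robustness on real tissue, which should be assessed with
`runEvaluate()` against expert scores.

## Evaluation statistics

`blandAltman()` reports the mean method-minus-reference difference
(bias), the sample (n−1) SD of the differences and the conventional
`bias ± 1.96 SD` limits of agreement (the 1.96 multiplier, not a
t-quantile, matching standard practice). The paired t-test uses
`t = bias / (sd/√n)` with `n − 1` degrees of freedom; two-sided by
default. On the bundled 33-region reference table this reproduces a
bias of 0.09, limits of agreement −2.91 to 3.10 and a two-sided
p = 0.728 — the published presentation of these limits drops the sign
of the lower limit, and labels the test one-sided although only the
two-sided computation yields the printed p-value; the package reports
the signed, two-sided quantities. The published 95 % confidence interval
for the bias and the published 0.91 correlation are not reproducible
from the table's ratio columns (the recomputed Pearson correlation is
0.36, and which paired quantities produced 0.91 is not stated);
`pearsonCorrelation()` is provided but no claim is asserted about those
two numbers.

One more discrepancy is worth recording: within the bundled table the
non-amplified region printed with ratio 2.59 (75/29) carries identifier
169284039, while the notes accompanying the original comparison
attribute that ratio — the false-positive case — to 169283911. The
package computes from the row data, so `misclassificationTable()`
reports 169284039 as the false positive and 168138203 (ratio 1.19,
expert-positive) as the false negative, two disagreements in total.
The table also repeats two identifiers with differing totals; all 33
rows are kept as printed because the agreement statistics only reproduce
over the full set, and `runEvaluate()` pairs repeated identifiers by
occurrence order.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based, row-major, pixel-center throughout; pixel
  arrays are `H × W × 3` with 8-bit values on `[0, 255]` at rest and
  floats in `[0, 1]` after normalization. Conversion back to 8-bit
  happens only at export, rounding half away from zero.
* All reported ratios round half away from zero to 2 decimals; R's
  default half-to-even would disagree with printed clinical tables on
  exact halves.
* Constant-channel images normalize to the lower bound with a warning.
  An all-background ROI scores as a structured failure ("no qualified
  nuclei", naming the stage that emptied the stream) rather than an
  error in batch mode.
* Zero total CEP17 over a selection is an error directing the caller to
  the fallback path; the fallback itself is applied during
  qualification, not scoring.
* Degenerate t-tests: zero-variance differences give `p = 0` for a
  nonzero bias and `t = 0` (two-sided `p = 1`) for a zero bias.

## Problem sizes used by the test-suite

The suite validates detection recall/precision on twenty 512 × 512
scenes of 10 nuclei, cluster decomposition on two 768 × 768 amplified
scenes with half the HER2 signals in clusters, the qualification flags
on a 20-nucleus scene with planted truncation and overlap, and
end-to-end ratio recovery on the full presets (30–45 nuclei) both
noise-free (tolerance 0.05) and at noise SD 4 (tolerance 0.1). These
sizes exercise every code path at the per-ROI scale the tool targets
while keeping a full test run in the low minutes.
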
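---
title: "Ear biometric identification with earmatch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear biometric identification with earmatch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reliable patient identification is a prerequisite for longitudinal health
care, yet in many low-resource settings no dependable identifier exists,
especially for infants, for whom fingerprinting and face recognition work
poorly. The external ear is a promising alternative: its shape is
individually distinctive, stable, and photographable with any commodity
smartphone. `earmatch` implements a complete closed-set ear-identification
pipeline: images are conditioned by a fixed preprocessing sequence, reduced
to sets of 128-dimensional keypoint descriptors ("vector maps"), enrolled
into a gallery, and probes are identified by ranking gallery records by
average nearest-neighbour squared Euclidean distance. The package also
ships the evaluation harness (rank-1..rank-10 recognition rates, a
strategy-ablation grid, a resize-parameter sweep) and a seeded synthetic
cohort generator so the entire pipeline is testable without any image
download.

## The matching model

An image yields a set of keypoint descriptors
$X = \{x_1, \dots, x_n\},\ x_i \in \mathbb{R}^{128}$. A probe $P$ is scored
against a gallery record $G$ by

$$ s(P, G) \;=\; \frac{1}{|P|} \sum_{p \in P} \; \min_{g \in G} \lVert p - g \rVert^2 , $$

the average over probe descriptors of the squared Euclidean distance to
their nearest neighbour in the record. Small scores mean strong matches;
$s(P,P) = 0$ exactly. The score is asymmetric: the probe side is averaged,
matching the operational direction "match the test image against the
training database". Candidates are sorted ascending and the ten smallest
are returned; the true subject at rank 1 is a top-1 (hence also top-10)
match, within ranks 2–10 a top-10 match, otherwise "no match".

Three properties of this model are load-bearing, and the test suite asserts
each directly:

* **Self-identification.** A gallery containing the probe's own composite
  verbatim is always ranked first with score exactly 0.
* **Superset monotonicity.** For any probe descriptor, adding rows to a
  record can only lower (never raise) its nearest-neighbour distance. This
  is the mechanism by which *keypoint concatenation* helps: descriptors that
  appear only under one capture angle find no close neighbour elsewhere and
  are diluted, while stable descriptors persist.
* **Rank invariance under monotone transforms.** Squared versus plain
  Euclidean distance changes scores but never changes ranks; the package
  keeps the squared form and score files record that convention.

Scoring is computed by an exact compiled brute-force search (`src/`): no
approximate index is used. Entries are visited in order of descriptor norm
and pruned with the bound $\lVert p-g \rVert^2 \ge (\lVert p\rVert -
\lVert g\rVert)^2$, which skips only candidates that provably cannot win, so
the result is identical to the naive double loop (the suite checks agreement
against an independently written R double loop to machine precision).

## Preprocessing

Stages run in a fixed, non-configurable order — grayscale, manual crop,
resize, histogram equalization — each independently switchable:

* **Grayscale**: ITU-R BT.601 luma ($0.299R + 0.587G + 0.114B$, rounded
  half up). The convention is pinned for cross-platform reproducibility.
* **Manual crop**: a rectangular ROI supplied as sidecar data (0-based,
  half-open coordinates, so widths are exact differences). Out-of-bounds
  ROIs are errors, never clamped. Automated ear segmentation is out of
  scope by design; crops are treated as human-supplied.
* **Resize to a fixed ear width** (default 150 px, height scaled to
  preserve proportions and rounded, minimum 1). Shrinking uses area
  averaging — which doubles as the mild noise-suppressing blur that makes a
  ten-fold downsize act like a median/Gaussian filter — and enlarging uses
  bilinear interpolation. The kernels are pinned because rank rates at
  this resolution are mildly sensitive to them.
* **Histogram equalization**: the intensity map
  $v' = \mathrm{round}\!\big((\mathrm{cdf}(v) - 1)/(N - 1) \cdot 255\big)$,
  anchoring the darkest pixel at 0 and spreading the cumulative
  distribution over the full 8-bit range. The map is monotone
  non-decreasing by construction. A constant image is the 0/0-degenerate
  case of any equalization formula; it is returned unchanged, the least
  surprising choice since every constant image is equally "equalized".

The stage order matters scientifically: equalizing an uncropped frame lets
the (typically bright) background dominate the histogram, compressing and
darkening the ear's intensity range and destroying keypoints — applying HE
before cropping is legal in the ablation grid precisely so this failure
mode can be measured.

## Descriptor backend

Keypoint extraction sits behind a small pluggable contract
(`descriptor_backend()`): `extract(pixels)` returns an $n \times 128$
descriptor matrix plus keypoint locations. The built-in `ghist` backend is
a deterministic multi-scale gradient-histogram extractor: keypoints are
strict local maxima of difference-of-Gaussians responses at four scales
($\sigma = 1.6 \cdot 2^{k/2}$), capped at the 400 strongest responses, and
each is encoded over a scale-proportional $16 \times 16$ sample lattice as
a $4\times4$ spatial grid of 8-bin gradient-orientation histograms with
Gaussian spatial weighting — then unit-normalised, clipped at 0.2,
renormalised and quantised to 8 bits. The descriptor is upright (no
rotation normalisation): captures in this protocol are stabilised by the
capture hardware to within a few degrees, and the 45°-wide orientation bins
absorb that jitter. Rows are kept in a canonical order (keypoint x, y,
scale, then lexicographic descriptor values) so extraction, caching and
concatenation are reproducible regardless of traversal order. Hyperparameters
live in the backend and participate in the configuration fingerprint, so
descriptors from different settings can never be mixed.

## Gallery, cache and privacy

A gallery stores subject records — ID, gender label, composite vector map —
and never pixels: possession of a gallery does not reveal what anyone's ear
looks like. Persistence is a single SQLite file with descriptors as 32-bit
floats, row-major; descriptor values are float32-quantised at enrollment so
`load_gallery(save_gallery(g))` reproduces `g` bit-exactly. Enrollment is
write-once: a duplicate subject ID is a conflict, and whether later visits
should update a stored composite is left to the caller (re-enroll under a
new ID or rebuild the gallery). All records in a gallery share one
preprocessing/backend fingerprint; loading a store under a different
configuration is an explicit error.

The descriptor cache is keyed by (raw image content hash, ROI,
configuration fingerprint). A rerun over cached inputs performs zero
backend invocations — observable through `extraction_count()` — and is
descriptor-for-descriptor identical to extraction from scratch.

## Evaluation protocol

Evaluation is closed-set: every probed subject is enrolled, and probes are
scored against the full gallery including their own record. The default
split enrolls the first half of each subject's captures (by capture index)
and probes the rest — with four captures this is two-enroll/two-probe; with
two, first-enrolls/last-probes. A `by_side` rule enrolls the first capture
of each ear side instead (one left + one right), the protocol used for
infant cohorts. When concatenation is enabled the enrolling captures merge
into one composite record and a subject's probe captures merge into one
composite probe; otherwise each probe capture is scored separately.
Rank-$k$ rates are cumulative counts of true ranks $\le k$, so
$r_1 \le r_2 \le \dots \le r_{10}$ always. Rates are written to CSV at two
decimals; full precision is kept in memory. Probes that yield no
descriptors are counted as "no match" and logged, never dropped.

The ablation runner evaluates a list of strategy presets on one shared
split. The built-in grids are the six-strategy progression
(resize only; resize+HE without crop; crop+resize; +HE; +concatenation;
+gender filter) and the five-strategy variant used for infant cohorts. The
gender filter restricts candidates to records whose label equals the
probe's before scoring; an unknown probe label disables the filter for that
query rather than erroring, so identification degrades gracefully. Because
filtering only removes competitors, a correctly labelled true match can
never be demoted by it — asserted as a paired property in the tests.

## The synthetic cohort generator

The generator exists so that every contract above is testable at desk scale
with known ground truth. Identity is modelled as a unique procedural
texture — curved concentric ridges with subject-specific frequency, angular
warp and phase, plus Gaussian blobs — on an elliptical support, evaluated
analytically on rotated coordinates (no resampling artifacts). Captures
vary the way field captures vary: rotation jitter (default ±3°, with an
optional 30° second-angle offset emulating a rotating capture shroud),
multiplicative brightness in 0.6–1.0 (a dimming battery), additive Gaussian
noise (sd 4/255), and bright-skewed high-contrast clutter outside the
ground-truth ROI (hair and skin highlights). The ear ellipse is sized so
the ROI covers about a third of the frame, matching a manual crop that
discards roughly two thirds of a raw capture. Defaults are calibrated once
so that on an $n = 30$ cohort the full technique stack saturates (rank-1
rate 1.0) while degraded configurations do not — disabling the crop with
clutter present drops rank-1 below 1.0, and resize+HE without a crop
collapses much further, reproducing the qualitative ordering expected of
the technique grid.

What the generator does *not* model: anatomical ear geometry, growth over
time, focus blur, perspective, or occlusion of the ear itself. Passing
tests therefore demonstrate that the pipeline's contracts and mechanisms
behave as specified, not that any particular accuracy will be attained on
real photographs — absolute rates on real cohorts depend on capture
hardware, crop quality and the descriptor backend.

## Numerical choices and degenerate inputs

* Intensity quantisation is round-half-up everywhere, clamped to [0, 255].
* A constant (contrast-free) image yields an empty, unmatchable descriptor
  set; enrolling a subject whose every image is unmatchable is an error,
  while an unmatchable probe is a logged "no match".
* Ranking ties are broken lexicographically by subject ID, making ranked
  lists deterministic across platforms.
* If fewer than `top_k` candidates survive filtering, the list is simply
  shorter; an empty post-filter gallery yields an empty list.
* Seeds: cohort generation consumes a single user-supplied seed; identical
  spec + seed is byte-identical on disk. The identification pipeline itself
  is fully deterministic.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every mechanism while staying quick on a single CPU: cohorts of
30 subjects × 4 captures (600×1200 px) for the end-to-end grid, 50-record
galleries for self-identification, 200 random descriptor-set pairs for
scorer verification, and 1,000 draws for the superset property. Rates on
cohorts this small move in steps of 1/30–1/60, which is ample for the
qualitative orderings the package asserts.
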
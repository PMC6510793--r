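---
title: "Simulated screening of porous library beads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated screening of porous library beads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadsort)
```

## The screening problem

One-bead one-compound (OBOC) peptide libraries are screened by incubating
porous resin beads (~100–300 µm diameter) with a fluorescently labeled
target protein, then collecting the beads that captured it. Because the
resin's pores restrict protein diffusion, the spatial pattern of captured
label is informative: small proteins fill a bead homogeneously, while large
proteins bind only in an outer corona, producing a "halo" whose width
shrinks as the protein grows. A dual-color design adds selectivity —
impurity proteins carry an orthogonal label, so a selective binder is
bright in the target channel and dark in the impurity channel.

`beadsort` reproduces, fully in silico, the computational half of an
automated microfluidic screen built around this readout: beads flow one at
a time into an imaging zone, a two-channel (red/green) 12-bit camera frame
is analyzed, and valves route each bead to a positive receptacle or to
waste. The package simulates the bead images, the detection/segmentation/
metric pipeline, the threshold classification, and the sorting loop, and
scores the result against ground truth.

## The synthetic bead generator

Seven labeled bead classes plus an unlabeled class are modeled
(`default_class_spec()`): homogeneous red, green and dual-color beads
(classes 1–3), red halo beads of decreasing width (class 4 broad, class 5
medium, class 6 narrow), and a green broad-halo class 7.

A rendered bead is a disk of diameter drawn from the polydisperse range
(default 100–300 µm at 1 µm/px) whose signal is

* frame background (default 0.05 normalized units) everywhere,
* plus, inside the disk, the class's radial label profile: a uniform value
  `peak` within the labeled shell — the outermost `halo_penetration`
  fraction of the radius — and `core_leak` inside it (`halo_penetration = 1`
  renders a homogeneous bead),
* optional angular modulation of the shell (a "partial halo", class 5) and
  a few bright adsorption spots on the corona (class 5),
* a per-bead lognormal labeling factor (sd 0.1) scaling the whole label
  signal, mimicking bead-to-bead variability in dye conjugation and
  protein adsorption,
* additive Gaussian camera noise (default sd 0.01 normalized units),
  quantized to 12-bit integers in `[0, 4095]`.

Halo penetration defaults are broad 0.55, medium 0.30 and narrow 0.04 of
the radius. Only the qualitative ordering (larger protein, narrower halo)
is physically constrained; the numbers were fixed once so that the three
halo geometries are separable by the percentile metrics below. The narrow
value matters most: the whole-bead 90th percentile only drops to the dark
core — making the homogeneity score large — when the bright shell covers
less than 10% of the bead area, i.e. penetration below ~0.05. A "narrow
halo" is therefore modeled as a thin, bright shell over a nearly dark
core, while the medium-halo class instead carries core leak, a partial
halo and bright corona spots, so the two classes differ in both core
signal and ring heterogeneity.

Unlabeled beads add no signal in either channel. They are consequently
invisible to fluorescence detection and flow to the negative outlet
undetected — the correct outcome, scored as true negatives.

What the generator does *not* emulate: optics (point-spread function,
out-of-focus light), bead aggregation and hydrodynamics, debris,
autofluorescence texture, and chemistry-specific labeling artifacts.
Passing tests therefore demonstrate the correctness and calibration of the
computational pipeline on idealized geometry, not performance on any
particular microscope.

## Detection and segmentation

`detect_bead()` runs a fixed pipeline per frame:

1. binarize each channel with a local first-order-statistic (local-mean)
   threshold — pixel > mean of its 51 px window + offset 0.02 — and take
   the union of the channels, so a bead labeled in either color is found;
2. remove connected components smaller than 100 pixels (background noise);
3. dilate (disc radius 3) and fill holes, reconstructing the disk from the
   thresholded ring/shell;
4. open and erode (disc radius 3), then dilate by 1 px, smoothing the
   boundary while keeping the mask within about a pixel of the thresholded
   support.

Local-mean windows are truncated and renormalized at frame borders
(integral-image box filter), never wrapped. The window width and offset
are configuration parameters (`segmentation_params()`); the defaults were
calibrated on synthetic disks so that the recovered mask area stays within
10% of the generating disk across the 100–300 µm range. Detection is
insensitive to overall intensity scale — halving all foreground leaves the
outcome unchanged — because the threshold adapts to the local mean.

Two further partitions feed the metrics:

* **Bright/dim strata** (`segment_bright()`): a pixel is bright when it
  exceeds 1.3 × the local mean computed over *bead pixels only*
  (multiplicative sensitivity, decreased relative to detection). A bead
  with no internal contrast yields an empty bright set, which is re-classed
  as entirely bright by convention — a uniform bead is a single brightness
  stratum, and its dim-stratum metrics fall back to whole-bead values.
  Stratification uses the per-pixel maximum of the two normalized channels
  so that green-only beads stratify as well.
* **Outer ring/core** (`outer_ring()`): the ring is the bead minus the
  bead eroded by `ring_fraction` (default 0.25) of the equivalent radius.
  The default was fixed so the ring of a medium-halo bead lies inside its
  labeled shell, making ring metrics sensitive to corona heterogeneity
  rather than to the shell edge.

## Metrics

All metrics are computed on normalized intensities (`raw / 4095`).
Percentiles use linear interpolation between order statistics (R's
`quantile` type 7); at realistic bead areas (>10^4 px) the interpolation
convention is immaterial. The panel (`extract_metrics()`, >20 metrics per
bead) includes for each channel the whole-bead 90th/95th/99th percentiles
and maximum, ring percentiles and maxima, means, medians, ring/core
ratios, and the homogeneity scores

\[
\alpha = \frac{M - P_{90}}{M},
\]

with `M` the regional maximum and `P90` the regional 90th percentile.
Small α means homogeneous fluorescence; large α flags a bright minority of
pixels — a halo shell or bright spots. α is scale-invariant and defined as
0 when `M = 0` (a fully dark region is maximally homogeneous). Suffixes
follow the field's convention: `alpha_er` = entire bead, red; `alpha_og` =
outer ring, green; `p90_dim_r` = 90th percentile of the dim stratum, red.

## Classification

`classify_bead()` evaluates a conjunction of strict inequalities over the
metric panel; `criteria_preset()` ships the validation and library screens'
printed thresholds (e.g. homogeneous red selection: `p90_er > 0.5` and
`p90_eg < 0.2`; narrow-halo selection: `alpha_er > 0.15`,
`alpha_er - alpha_eg > 0`, `p90_eg < 0.1`). Ties at a threshold are
negative by construction — the printed criteria are strict inequalities,
and ties are measure-zero on real data though constructible in tests.
Criteria serialize to YAML so operators can define new hyperplanes without
code changes.

## K-means discrimination of the ambiguous halo classes

The medium- and narrow-halo classes are deliberately similar; they are
discriminated unsupervised with `kmeans_discriminate()`: k = 2, features
standardized, 10 seeded restarts keeping the best within-cluster sum of
squares, maximum 300 iterations, tolerance as in `stats::kmeans`. The
canonical feature pair is the whole-bead 99th-percentile red intensity and
the 90th percentile of the dim stratum in red — the narrow-halo class has
a nearly dark core (low dim-stratum signal) while the medium-halo class
leaks label into the core. Accuracy against ground truth is computed under
the better of the two cluster-label permutations (cluster ids are
arbitrary), so it is bounded below by 0.5; the degenerate all-points-equal
case returns the majority-class fraction with a warning.

`rank_metrics()` reconstructs the metric-screening step with an absolute
standardized mean difference. On synthetic tables the dim-stratum metric
ranks near the top, but the 99th-percentile red intensity does not: the
selection criteria force medium-halo corona spots to be nearly as bright
as the narrow shell, so the top-1% pixel intensity hardly differs between
the classes and scale-invariant metrics (α, ring/core ratios) dominate the
ranking. The chosen pair nevertheless separates the classes essentially
perfectly, which is what the clustering requires.

## The sorting loop

`run_sort()` replays the screening flowchart as a logical state machine
with four valve configurations (load, trap, route-positive,
route-negative); hydraulics are abstracted away. Undetected frames never
leave the load state and their contents flow out through the open negative
outlet. Detected frames are trapped, every detected component is
classified, and the frame routes positive if *any* component is positive:
co-entering beads are routed jointly, so a mixed pair necessarily produces
one false routing — the device's documented error mode, reproduced rather
than corrected. Per-bead truth is still scored individually.

Reported figures: yield = true positives / positives fed; accuracy = true
positives / total beads collected at the positive outlet. With no
positives fed the yield is undefined (`NA`, never 0); with nothing
collected the accuracy is vacuously 1. Conservation identities
(`TP + FP = collected`, `TP + FN = fed`) are asserted in the test suite on
every run. Bulk mode collects positives in a common flask; single-bead
mode emits a pause event per positive and assigns wells A1…H12, wrapping
with a warning past 96. Timing is event-counted; the physical device's
throughput (~125 beads/hr, ~2.5 beads/min) is not modeled as wall-clock
time.

## Problem sizes and numerical choices

The shipped simulations use 350 × 350 px frames at 1 µm/px (the imaging
zone width), mimetics of roughly 60–100 beads matching the validation
screens' compositions, and 30 + 30 beads for the clustering experiment —
sizes at which every quantity of interest is stable to well under the
decision margins. All randomness flows from a single user seed: mimetic
streams are regenerated bit-identically from their spec, and K-means
restarts are seeded. Degenerate inputs are defined rather than left to
chance: empty masks error, `ring_fraction` 0 and 1 give empty ring/core
respectively, dark regions have α = 0, and a uniform bead is one bright
stratum.

## Known limitations

* The generator's halo geometry is stylized (sharp shell boundaries,
  circular beads); real halos decay smoothly and beads deviate from
  circularity.
* Green-channel α on unlabeled-in-green beads is a noise statistic
  (≈0.3 at the default background and noise); criteria comparing red
  against green α rely on the red score clearing it, which the narrow- and
  medium-halo geometries do by a wide margin, but heavily attenuated real
  signals may not.
* The bright/dim stratification inherits the local-mean window; beads much
  smaller than the 51 px window stratify coarsely.
* Throughput, pressure control and hardware failure modes are out of
  scope.
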
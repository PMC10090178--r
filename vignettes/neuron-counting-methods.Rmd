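---
title: "Counting pyramidal neurons: the model behind nisslcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting pyramidal neurons: the model behind nisslcount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nisslcount)
```

## The problem

Nissl staining marks neuronal somata dark on a light background. In the
hippocampal pyramidal layer, the cells of interest — pyramidal neurons — sit
among three recurring false-positive classes that any automated segmentation
picks up: weakly stained extracellular material, glial cells (much smaller
somata, around 7 µm), and *neuron profiles*, partial somata cut by the
microtome so that only a cap of the cell is present in the section.
`nisslcount` implements a high-throughput pipeline that segments candidate
somata in 2D partition images, removes the false-positive classes with two
automated filters, and reports the number of kept segmentations as the
partition's neuron estimate. An in-silico optical fractionator provides the
stereological counterpart against which those estimates are compared.

Because no public image set accompanies this problem, the package carries a
first-class synthetic-tissue generator with exact ground truth; every stage
is validated against it.

## The filtering model

Segmentation (a pluggable backend; the shipped classical backend is a
Gaussian-smooth → Otsu → distance-transform → watershed chain) produces an
instance label map. Each instance then receives a moment-matched ellipse:
with $C$ the 2×2 central covariance matrix of the instance's pixel
coordinates, each full axis length is $4\sqrt{\lambda_i}$ for the
eigenvalues $\lambda_i$ of $C$. For a filled disc of radius $r$ the
coordinate variance is $r^2/4$, so both axes recover the diameter $2r$. The
*minor* axis is the width of the soma and serves as the neuron-diameter
proxy throughout.

Two filters run in a fixed order:

1. **Intensity.** On the inverted image, the mean gray value of the whole
   partition (tissue and background, inside the ROI mask) is the threshold;
   instances whose mean gray is strictly below it are removed as
   extracellular material. The boundary case (exactly at the threshold) is
   kept; both conventions are recorded in the output metadata.
2. **Diameter.** Over the intensity survivors, the mean $\mu$ and sample
   standard deviation $s$ (with $n-1$ denominator) of the minor-axis
   diameter are estimated per partition, and instances strictly below
   $\mu - k\,s$ are removed. The default multiplier is $k = 0.75$. There is
   deliberately **no upper threshold**: overlapping neurons segmented as one
   object are counted as one, which trades a small undercount for robust
   rejection of glia and profiles.

Diameter statistics are computed on intensity survivors only; faint
background artifacts would otherwise corrupt $\mu$ and $s$. Whether the
statistics should be estimated before or after intensity filtering is a
genuine design choice; this package estimates after, records both applied
thresholds in its outputs, and exposes a frozen-statistics mode
(`diameter_filter(..., stats = )`) so that re-filtering a kept set under the
first pass's thresholds is exactly idempotent — the testable contract.

In vignette mode (the 750 µm × 750 µm assessment crops) an additional edge
rule removes any instance touching the image border, matching how manual
raters treat edge neurons.

Every instance keeps a persistent id through all passes; the ledger CSV
contains kept and removed instances with their removal reasons, so every
tally is auditable: `n_kept` is the partition's automated neuron estimate.

## The optical fractionator

The stereological counterpart estimates the neuron number of an ROI from
systematically sampled counting frames:

$$N \;=\; \Sigma Q \cdot \frac{\bar t}{h} \cdot \frac{1}{asf} \cdot \frac{1}{ssf}$$

where $\Sigma Q$ is the number of nucleoli counted in the disectors, $\bar t$
the measured section thickness, $h$ the disector height, $asf$ the area
sampling fraction (frame area over grid-cell area) and $ssf$ the section
sampling fraction. Defaults: 50 µm × 50 µm frames, $h = 10$ µm, two 3 µm
guard zones, $ssf = 1$, thickness 20.39 µm, and a grid spacing derived from
the ROI area and a target of 10 frames. $\bar t$ is the $Q$-weighted mean of
per-frame thickness measurements (the common stereology-software
convention); the arithmetic mean is available via
`fractionator_params(t_bar_method = "arithmetic")`.

The classic unbiased counting frame has inclusion and exclusion edges so
each particle can be counted in exactly one frame. For point-like nucleoli
this reduces to a half-open frame — $x \in (x_0, x_0+w]$,
$y \in [y_0, y_0+h)$ — which is adopted here precisely because it makes the
tiling property exactly testable: under an exhaustive tiling every nucleolus
is counted once and only once, and the estimate equals the true count on
every replicate.

Two geometric conventions matter for unbiasedness and are deliberate:

* A frame is placed at every grid node whose **node point** falls inside the
  ROI polygon (point-sampled frame placement). Frames near the boundary may
  then extend outside the ROI and count outside particles, while inside
  particles near the boundary are occasionally missed; the two effects
  cancel in expectation provided the particle process is homogeneous for at
  least one frame width beyond the ROI. The synthetic validation slabs
  therefore extend 100 µm beyond the counting ROI.
* The nucleolus of each synthetic neuron is placed uniformly in the
  **equatorial disc** of half the somal radius rather than a full sphere:
  this keeps the marginal depth distribution of nucleoli exactly uniform
  through the section, which is the sampling assumption the disector relies
  on, while remaining trivially inside the soma.

## What the synthetic generator emulates — and what it does not

`slab_spec()`/`generate_slab()` place cells by homogeneous Poisson processes
(per class) through a 20.39 µm slab. Defaults: pyramidal somata at
400/mm² with log-normal minor diameters (median 18 µm, `sdlog` 0.15 —
at the pipeline's 0.75 µm pixels the median soma is 24 px wide, the
segmentation backend's default diameter); glia at 100/mm² (median 7 µm);
faint extracellular blobs at 50/mm² drawn within ~8 gray levels of the
background; 10% of neurons planted as touching pairs (centre distance below
the mean somal radius). The class mixture was chosen so that roughly a
quarter to a third of segmented objects are planted false positives, the
regime the filter is designed for. Somata are ovoid (aspect ratio sampled in
[1, 1.6]) and the filter operates on the minor axis, so the planted
"diameter" is the minor axis. Stain intensities put neurons ≥ 30 gray levels
below background, glia in between, and blobs near background, exercising the
intensity filter.

`render_partition()` projects a slab onto one focal plane. Somata within a
fifth of their radius of a cut face are rendered as profile discs with the
cap cross-section $2\sqrt{h(2r-h)}$ at cap height
$h = \max(\text{face distance}, 0.05\,r)$ — emulating caps of somata centred
in adjacent sections while keeping all bookkeeping on cells inside the slab.
This makes profile minor diameters fall clearly below in-plane neuron
minors; on default partitions the two distributions overlap by well under
10% of their mass, which is what makes a single per-partition diameter
threshold a sensible model.

Not emulated: optics (no point-spread function), staining chemistry,
intensity gradients, texture inside somata, anisotropic shrinkage, or true
3D rendering beyond the plane-intersection profiles. Passing tests therefore
show that the pipeline's logic is correct under its stated model of the
data, not that the shipped classical backend matches a trained network's
accuracy on real slides.

## Numerical choices and degenerate inputs

* Ellipse fits use population (n-denominator) moments; degenerate pixel sets
  (single pixel, collinear) get a minor axis of 1 px by decree.
* Both filters use strict inequalities at their thresholds.
* Auto-contrast saturates 0.35% of pixels per side by default (the common
  interactive-software default); constant images pass through unchanged.
* Inversion precedes contrast adjustment; the order is recorded in each
  partition's metadata since the opposite order is equally defensible.
* Otsu-based classical segmentation declares a partition empty when the
  between-class mean separation is below 0.15 of the intensity range,
  preventing pure noise from being split into spurious instances.
* The "flexible" segmentation diameter is estimated as twice the median
  distance-transform peak height of a pilot pass.
* Ground-truth matching for detection metrics is one-to-one on descending
  IoU with a 0.5 gate; at that gate matches are provably unique, so the
  greedy assignment is optimal.
* Empty-vs-empty masks score Dice 1 with a warning (vacuous agreement);
  empty-vs-nonempty scores 0.
* Paired Wilcoxon with all-zero differences is reported as degenerate with
  p = 1 rather than erroring.
* The Dice group comparison defaults to the independent (Welch) two-sample
  t-test, with the paired form behind a flag; the report records which form
  was used.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to make every Monte-Carlo check statistically meaningful:

* Stereology unbiasedness: a 1700 µm slab with ~1000 neurons inside a
  1500 µm counting ROI, 200 independent grid offsets at 150 µm spacing
  (~100 frames each), so the replicate mean estimates the bias with ~1%
  standard error. The sparse 10-frame default remains the per-partition
  counting design; the dense grid is the validation harness.
* End-to-end comparison: 30 partitions of 600 µm spanning a 10-fold planted
  density range (120–1200 neurons/mm²). The simulated stereology uses a
  75 µm grid on these 0.25 mm² partitions so that per-partition counting
  noise is comparable to ~10-frame sampling of full-size partitions; with a
  literal 10-frame design on partitions this small, $\Sigma Q$ is a handful
  and the stereology count itself would carry 30–100% noise, swamping any
  estimator's rank agreement.
* Filter recovery: three default partitions, judged on the ground-truth
  instance maps against the planted class ledger (sensitivity on in-plane
  neurons, rejection on glia + profiles + blobs).

## Known limitations

* The classical watershed backend is a deterministic stand-in for a trained
  generalist segmentation model; it under-segments dense clusters and its
  detection F1 is insensitive to ±1–3 px changes of the diameter parameter,
  so pilot sweeps over adjacent diameters rank settings within a noise band.
  A model backend can be registered via
  `options(nisslcount.model_backend = )`.
* Overlapping neurons are counted as one by design; estimates are therefore
  systematically below true counts in dense tissue, which is why the method
  comparison is rank-based.
* The coefficient of error of the fractionator is out of scope (single
  partitions, ssf = 1), as are stain normalization, whole-slide formats,
  and any training or fine-tuning of segmentation networks.
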
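---
title: "Quantifying cytoplasmic marker expression around segmented nuclei"
author: "cytoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytoplasmic marker expression around segmented nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoring)
```

## The problem and the model

Cytoplasmic markers — insulin, C-peptide, glucagon in islet biology,
cytokeratins in epithelia — concentrate in a thin rim around the nucleus.
A nuclear mask alone therefore under-samples the signal, while whole-cell
segmentation is hard in densely packed tissue where membranes are not
stained. `cytoring` adopts the widely used compromise: segment what is
easy (nuclei on a DAPI channel), then expand each nucleus label by a fixed
physical distance $d$ (default $d = 1\,\mu m$) and treat the resulting
interspace annulus as a proxy for the perinuclear cytoplasm.

For cell $i$ and channel $c$ the pipeline measures integrated intensity
and area twice, without and with the enlargement, and derives the ring
mean without re-touching pixels:

$$
I_{\mathrm{new}}(i,c) \;=\;
\frac{\mathrm{IntDen}_{\mathrm{with}} - \mathrm{IntDen}_{\mathrm{without}}}
     {\mathrm{Area}_{\mathrm{with}} - \mathrm{Area}_{\mathrm{without}}}.
$$

This identity is exact (it is the mean over the set difference of the two
pixel sets) and is verified against a per-pixel oracle in the test suite.
A second method, `expanded_mean` (the plain mean over the whole expanded
footprint), is retained as a config option because descriptions of
comparable pipelines do not always pin the formula down; the choice is
recorded in run manifests. Cell $i$ is called positive for marker $c$ iff
$I_{\mathrm{new}}(i,c) > T_c$ — strictly, so ties classify negative.
Thresholds are user-supplied raw-intensity values, conventionally
$0.6\times$ a manually measured representative intensity
(`derive_threshold()`); automatic threshold selection is deliberately out
of scope, as is inter-sample statistics.

## Expansion semantics and the double-positive artifact

The expansion radius is $d / \text{pixel size}$, kept fractional — no
rounding, so results do not jump discontinuously with calibration.
Distance is Euclidean between pixel centers with the $\le$ comparator
(boundary pixels included). Two modes exist:

- **independent** (default): each label is dilated as if alone; a
  background pixel joins label $L$ iff it lies within the radius of $L$'s
  nearest pixel, regardless of other labels. Footprints of touching cells
  overlap, and shared pixels are measured by *both* cells. This is
  faithful to per-ROI enlargement in interactive tools, including its
  documented failure: where an A-only cell touches a B-only cell, the A
  cell's ring samples the neighbour's B shell, inflating double-positive
  (bihormonal) counts — a serious issue because true bihormonal cells are
  rare events.
- **exclusive**: pixels within reach of several labels go only to the
  nearest one (exact ties to the smaller label id, which is deterministic
  because labels are renumbered in scan order). Footprint unions are
  identical between modes; exclusive mode simply partitions them.

Independent mode is the default on fidelity grounds; the mitigation is
opt-in. The acceptance suite builds adjacency scenarios of single-positive
pairs and asserts the direction: independent-mode false double positives
are never fewer than exclusive-mode ones, and strictly more on at least
one image.

Whether the per-ROI enlargement of the original interactive tools uses
Euclidean or polygon-offset geometry is not documented; Euclidean
distance-transform semantics were chosen and are stated here once.

## Segmentation

The classical backend is fully deterministic: ROI-masked nuclear channel →
separable Gaussian smoothing (`smooth_sigma_um`, default 0.25 µm — small,
so that 1–2 px background gaps between touching nuclei are not bridged) →
Otsu threshold on 256 bins spanning the data range (binning relative to
the range makes segmentation invariant to positive intensity rescaling; a
`fixed` absolute threshold is available) → 8-connected components →
seed splitting on the exact Euclidean distance transform (seeds are
distance maxima greedily suppressed within `split_min_distance_um`,
default 4 µm ≈ half a typical islet nucleus diameter plus margin; pixels
go to the nearest seed) → removal of objects below `min_area_um2`
(default 4 µm², debris-sized). Nuclei touching the image border are kept
and flagged, since silently dropping them would bias total counts.

A `stardist` backend name is reserved as an adapter seam; in this
installation it raises a structured backend-unavailable error instructing
fallback, because no StarDist runtime exists in the deployment
environment and re-implementing the network is a non-goal. The optional
user ROI is applied *before* thresholding and again to the label output;
whether comparable pipelines mask before or after segmentation is not
documented, so this choice is stated rather than assumed unique.

## What the synthetic generator emulates — and what it does not

`simulate_image()` renders the stated world the tests live in: a
256 × 256 px field at 0.5 µm/px with 50 cells, nucleus semi-axes
2.5–4 µm with axis ratios 0.75–1 and random orientation, rejection-sampled
centers honoring a 1 µm edge-to-edge gap (dense, islet-like, but
non-overlapping), 1.5 µm cytoplasmic shells, positive shells at intensity
200 and negative at 25 on an 8-bit-like scale over background 5, additive
Gaussian noise (sd 2 by default, 0 in the noiseless regimes) clipped at
zero. These values were fixed a priori as a realistic confocal islet
section; the ground-truth-recovery tests use threshold 100 so positives
sit at 2× threshold and negatives at 0.25×. All randomness flows through
a pinned Mersenne-Twister generator, so one seed reproduces bit-identical
images across platforms.

The generator deliberately omits optics (no PSF, no photobleaching, no
depth attenuation), autofluorescence texture, irregular nuclear shapes
and chromatin texture, and 3-D structure. A green end-to-end test
therefore establishes that the *measurement and classification logic* is
correct given a segmentation, and that the pipeline's failure mode has
the documented direction — it does not certify segmentation accuracy on
real microscopy, which depends on staining quality and is the user's
responsibility to spot-check.

## Numerical and design choices

- **Calibration** is mandatory (argument > TIFF resolution metadata >
  error) and must be isotropic in-plane; anisotropic files are rejected
  rather than averaged, because "1 µm in all directions" is not
  well-defined on an anisotropic grid.
- **Empty regions** (a ring fully clipped at the border, or a sub-pixel
  radius) yield NaN intensity sentinels, never 0 — a 0 would silently
  classify as negative. Ring-degenerate cells fall back to the nucleus
  mean, carry a flag through classification, and are warned about; every
  warning is echoed in the run manifest.
- **Tie-breaks** are all deterministic: Otsu takes the first
  between-class-variance maximum; components and labels are numbered in
  scan order; exclusive-mode distance ties go to the smaller label.
- **CSV schema** (area in px and µm², mean/integrated/min/max intensity,
  centroid, border flag, calibration) supersets the classic Measure
  columns the downstream formula needs; the pairing convention
  `{sample}_ch{k}_{without|with}_enlargement.csv` is fixed by this
  package. Numeric output is locale-independent; round-trips are lossless
  to at least 6 significant digits.
- **Percentages** use total segmented cells in the analyzed ROI as the
  denominator; per-marker positive counts include multi-positive cells.
  With zero cells, percentages are NA, not 0.
- **TIFF support** is a minimal built-in baseline reader/writer
  (uncompressed grayscale pages, 8/16-bit, both byte orders, multi-strip,
  ImageJ hyperstack metadata) because the deployment environment offers
  no TIFF-capable R package; compressed, interleaved-colour or float
  TIFFs are rejected with explicit errors. A third-party reader is used
  in the test suite to confirm interoperability of the writer.

## Known limitations

- No volumetric analysis: Z-stacks are always projected (max or mean).
- The ring proxy under-represents cytoplasm for elongated or polarized
  cells, and misattributes signal wherever a neighbour's cytoplasm enters
  the ring (see the artifact section; exclusive mode reduces but cannot
  eliminate this, since it partitions territory by distance, not by true
  cell boundaries).
- Thresholds are global per channel; intensity drift across a slide is
  not modeled or corrected.
- The classical segmenter is adequate for well-stained, roughly convex
  nuclei; heavily clumped or irregular nuclei need a learned segmenter
  behind the adapter seam.
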
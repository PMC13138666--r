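---
title: "Counting hemocytometer cells from phone photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting hemocytometer cells from phone photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A hemocytometer is a counting slide with four chambers, each etched with a
1 mm² grid under a coverslip at 0.1 mm depth, so each chamber grid overlies
a volume of 0.1 mm³ = 10⁻⁴ mL. Cell concentration follows from the mean
count per chamber:

$$ C \;=\; \bar{n} \times d \times 10^{4} \ \text{cells/mL}, $$

where $\bar{n}$ is the mean cell count over the four chambers and $d$ the
dilution factor. Manual counting under a microscope is slow and
observer-dependent; `hemocount` automates it for photographs taken with an
ordinary phone camera held to the eyepiece. Such photographs contain the
chamber grid somewhere inside a cluttered frame (bench, hands, labels,
vignetting), so the pipeline has two stages:

1. **ROI extraction** — hierarchical region proposals classified by a small
   convolutional network locate the counting-grid region of interest.
2. **Cell counting** — grayscale conversion, morphological opening, Canny
   edge detection, a Hough circle transform, and perimeter verification
   detect and count the (roughly circular) cells in the cropped chamber.

The package targets cultured lines such as PC3, LN-CaP and DU-145, whose
cells are well approximated by dark discs within a narrow radius band.

## Synthetic scenes and what they do (not) capture

No public photograph corpus accompanies this problem, so the package ships
a seeded generator (`makeChamberImage`, `makePhoneImage`, `makeClutterImage`,
`makeTrainingSet`) whose output carries exact ground truth; every stage of
the pipeline is validated against it.

A chamber scene is a bright field (default intensity 200) with a dark ruled
grid (intensity 120, period 50 px, width 2 px) and `nCells` dark
anti-aliased discs (intensity 60, radii uniform in 6–10 px), placed by
rejection sampling so all pairwise center distances are at least
`minCenterSeparation` (default 20 px = 2 r_max, guaranteeing
non-overlapping cells). A linear illumination fall-off (10 % across the
diagonal) and additive Gaussian noise (sd 5 gray levels) follow. The
defaults — 400 × 400 px scenes with 50 cells — are the package's benchmark
condition: about the cell density at which a chamber square is comfortably
countable by eye, with radii chosen so a cell spans roughly a tenth of a
grid square. A phone scene embeds the chamber at a random offset in a
larger canvas (default 800 × 800) of clutter: low-frequency mottle, random
rectangles at object scale, and text-like strokes.

The generator is a pure function of its `SceneParams` (one private RNG
stream per call, seeded explicitly; the global RNG is untouched), so every
fixture is reproducible byte for byte.

What it deliberately does **not** emulate: lens distortion, JPEG artifacts,
perspective skew, overlapping or touching cells, debris that mimics cells,
and out-of-focus blur. Passing the synthetic benchmark therefore
demonstrates that the algorithmic chain is correct and calibrated for
well-formed inputs; it does not certify performance on real phone
photographs, where ROI lighting and cell clumping dominate the error
budget.

## ROI extraction

### Region proposals

`proposeRegions` mirrors the structure of selective search: the image is
downscaled (longest side ≤ 200 px), segmented into coherent regions by
graph-based Felzenszwalb–Huttenlocher segmentation (8-connected pixel
graph, edge weight = intensity difference, adaptive threshold
$\mathrm{int}(C) + k/|C|$ with $k = 300$, minimum segment 20 px), and the
regions are merged bottom-up, most similar adjacent pair first. Similarity
is the sum of intensity similarity ($1 - |\mu_i - \mu_j|/255$), size
preference (small regions merge early) and bounding-box fill, as in the
original algorithm. The bounding box of every node in the merge tree is a
proposal; boxes born later (coarser groupings) rank first, which puts
whole-object boxes — such as the complete chamber — near the top of the
list. Proposals are deduplicated, bounded to the image, and capped at
`maxProposals` (default 200).

### Classifier

The classifier is a sequential network: two convolutional layers with small
square kernels (2 × 2 by default; 256 then 128 filters at full size), each
followed by batch normalization, ReLU and 2 × 2 max pooling, dropout after
the convolutional stack (rate 0.25), then a dense head 128–128–64–2 with
batch normalization on the first two dense layers, dropout (0.5) after the
second, and a softmax over the two classes (0 = Non-ROI, 1 = ROI). Where
the exact placement of normalization and dropout was open, the layout above
was fixed once and surfaced in `ClassifierConfig`. Inputs are crops resized
to the configured input size (aspect ratio not preserved — the chamber is
roughly square, and a fixed resize keeps the classifier's input contract
trivial) and scaled to [0, 1].

Training (`trainClassifier`) follows a fixed protocol: categorical
cross-entropy, Adam (learning rate 10⁻³), 10 epochs, batch size 32, a
seeded 90/10 train/validation split, and horizontal flips as the only
augmentation — ROI-ness is flip-invariant by construction. All randomness
(initialization, shuffling, dropout, flips) derives from one seed, so runs
are exactly reproducible. The implementation (im2col convolution and
pooling in compiled code, the rest in R) is part of the package; models
serialize to RDS with a JSON sidecar describing both configurations.

Problem sizes: the package default mirrors the full-size architecture
(256 × 256 × 3 input, 256/128 filters), which the tests exercise for its
structural contracts (shapes, softmax normalization, seeded
reproducibility). Behavioural training runs — the test suite and the
acceptance script — use a reduced instance chosen as this package's
CPU-scale study condition: 48 × 48 grayscale input, 32/16 filters,
64–64–32–2 dense head, trained on 400 generated crops. At 48 px the grid
ruling and cell texture survive downscaling, and one training run completes
in about a minute on a laptop core; the protocol (epochs, batch, split,
augmentation) is unchanged.

### Training classes and the selection policy

ROI examples are random crops of chamber scenes (side 0.3–1 × the scene's
smaller dimension). Non-ROI examples combine clutter-only crops with
"undesirable" mixed crops from phone scenes in which the chamber covers
less than 35 % of the window (one third of the class). The mixed negatives
matter: with clutter-only negatives the classifier calls *any* window that
contains part of the chamber an ROI, and oversized chamber-plus-background
boxes cannot be rejected.

`extractRoi` classifies every proposal and returns the **largest-area
proposal whose ROI probability reaches the threshold** (0.5), ties broken
by score. A score-first policy was tried and discarded: a well-trained
classifier saturates near 1 on any pure chamber crop, so a single grid
square can outscore the full chamber by 10⁻⁴ and score ordering degenerates
to noise. The binary label carries the usable information — mixed and
clutter boxes fall below threshold — and among accepted boxes the largest
is the fullest chamber view. If nothing is accepted, `extractRoi` signals a
`hemocount_noRoiFound` condition; `runCount` can fall back to counting the
whole image.

The residual end-to-end error mode is a selected box slightly smaller than
the chamber, which clips cells at the crop border — an ROI-stage error, not
a counting one.

## Cell counting

`countChamber` composes five stages; all tunables live in `CounterConfig`.

**Grayscale.** ITU-R BT.601 luminance (0.299 R + 0.587 G + 0.114 B).

**Morphological opening.** Erosion then dilation with a 3 × 3 square
structuring element (configurable to a disc). Grayscale erosion/dilation
are the neighborhood minimum/maximum, which on 0/1 images reduce exactly to
the set-theoretic rules — output 1 iff the element *fits* (erosion) or
*hits* (dilation) the foreground. Borders are reflected (symmetric
half-sample), so the operators are defined on the full image; opening is
idempotent and anti-extensive, and both facts are asserted in the tests
against literal double-loop evaluation of the definitions. Opening strips
bright speckle noise smaller than the element while leaving cell-scale
structure intact, which stabilizes the subsequent edge map.

**Canny edges.** Gaussian smoothing (σ = 1), Sobel gradients, non-maximum
suppression along the quantized gradient direction (plateau ties keep a
single pixel, so a clean step yields a one-pixel line), and hysteresis:
pixels above the high threshold seed edges, pixels between the thresholds
survive only when 8-connected to a seed. The thresholds couple to the
Hough edge-strength parameter as high = `param1`, low = `param1`/2 — the
standard 2:1 hysteresis coupling — and can be overridden independently.

**Hough circle transform.** Circles satisfy $r^2 = (x-a)^2 + (y-b)^2$. On
grayscale input the transform votes along the gradient direction: each edge
pixel casts votes at ±r along its unit gradient for every radius in
[`minRadius`, `maxRadius`] (defaults 4–12 px, bracketing the generator's
6–10 px band). Center candidates are accumulator local maxima with at least
`param2` votes (default 18 — roughly a third of the perimeter of the
smallest expected cell), thinned so no two centers lie within
`minCenterDist` (default = `minRadius`); the radius is the mode of edge
distances in the annulus. Gradient voting is what makes grid lines cheap to
reject: straight edges spread their votes along a line and never
concentrate at a center. Raising `param2` provably never adds detections
(the candidate set shrinks and the greedy suppression order is preserved).

When the input is already a binary edge map there is no interior gradient,
so the transform falls back to the classic full accumulator: one vote layer
per radius, candidates are per-layer local maxima (votes = distinct
supporting edge pixels). The per-radius layering matters — summing layers
blurs the true peak into off-center ridges.

**Perimeter verification.** Each candidate is checked against the edge map:
64 points sampled on its perimeter, support = fraction with an edge pixel
within 1 px, accepted when support ≥ 0.3. This is the conditional check
that removes accidental accumulator peaks (e.g. at grid-line crossings,
whose support comes from two thin arcs only), and raising the threshold is
again monotone. Circles whose center lies in the crop are counted even if
the rim is clipped; no boundary-line inclusion rule is applied beyond
that, since the counting convention is the generic mean-per-chamber × 10⁴
formula.

`aggregateReport` enforces the four-chamber protocol (overridable),
computes the total, mean and concentration, and serializes to JSON;
`drawOverlay` writes the conventional red-circle overlay.

### Calibration

`param1` = 60, `param2` = 18, radius band 4–12 px and support threshold 0.3
were fixed once against the synthetic benchmark (10 scenes × 50
non-overlapping cells): the configuration counts every scene within 5 %,
with the grid-only control (0 cells) at exactly 0. Real images with
different optics would need the radius band re-estimated — it is the one
parameter tied directly to magnification; per-cell-line presets share these
defaults until line-specific data exist.

## Evaluation metrics

For the two-class ROI problem the package computes, one-vs-rest per class,
precision TP/(TP+FP), recall TP/(TP+FN) and F1 = 2PR/(P+R); overall
accuracy (TP+TN)/total; macro averages (unweighted class means) and
weighted averages (support-weighted means). Metrics with a zero denominator
are reported as 0 with a warning — degenerate inputs should be loud but not
fatal. Reports print as a plain-text table rounded to two decimals (raw
values are retained in the object) and serialize to JSON. Counting runs are
scored as accuracy = measured/actual × 100 with companion error
|100 − accuracy|, so over- and under-counts are penalized alike.

The test suite cross-checks every metric against an independent reference
implementation (caret) on randomized confusion matrices, and asserts the
two identities that catch most bookkeeping mistakes: weighted recall equals
accuracy in the one-vs-rest two-class setting, and macro equals weighted
under balanced supports.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (x = column, y = row); boxes are half-open
  [x0, x1) × [y0, y1). All conversions to R's 1-based indexing happen at
  the array boundary.
* Images are plain numeric arrays in 0–255; PNG/JPEG I/O scales at the
  file boundary.
* Morphology and blur pad by symmetric reflection; resize is bilinear with
  center-aligned sampling (an identity at equal sizes).
* Candidate ordering everywhere (Hough suppression, proposal ranking) is
  fully deterministic: votes/level first, then row-major position.
* Rejection sampling of cell placements fails with an explicit placement
  error after a bounded number of attempts rather than looping forever.
* An empty edge map yields an empty detection table, not an error; a
  clutter-only photograph yields a typed no-ROI condition.
* Batch-norm inference uses running statistics (momentum 0.9); a batch of
  one trains with zero variance and the ε = 10⁻⁵ guard.

## Known limitations

* Touching or overlapping cells are counted as one circle each at best; no
  declumping is attempted (the counting model is circles only).
* No live/dead discrimination or per-type morphology; the cell-type label
  is metadata with identical defaults until line-specific calibrations
  exist.
* The classifier is intentionally small and trained on synthetic scenes;
  transfer to real photographs requires retraining on a real `ROI/` /
  `Non_Roi/` directory via `runTrain`.
* Validation accuracy saturating at 1.0 on the synthetic set says the two
  synthetic classes are separable — real-image curves would sit lower.
* The whole-image fallback after a no-ROI outcome preserves throughput but
  can count clutter; it is switchable off (`--no-fallback`).
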
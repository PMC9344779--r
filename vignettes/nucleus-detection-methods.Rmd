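---
title: "Detecting basal-lineage nuclei in Papanicolaou-stained cytology: methods and design choices"
author: "cytodetect"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Detecting basal-lineage nuclei in Papanicolaou-stained cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In Papanicolaou-stained oral cytology, basal-lineage cells stain blue and
superficial cells stain red/orange. Because cellular atypia raises the
nucleus-to-cytoplasm (N/C) ratio, automatically finding the *nuclei of the
blue-stained cells* is the first step toward machine-assisted cytological
screening. `cytodetect` implements and compares two detector families for
that task:

1. a **sliding-window pipeline**: the image is tiled into 96 × 96 px
   windows on a non-overlapping grid, a convolutional patch classifier
   scores each window for "contains a nucleus", and windows are
   highlighted above probability bands (red above 0.9, yellow above 0.5);
2. an **instance segmenter** that proposes per-nucleus masks directly.

Both are evaluated with the same four matched-region criteria: number of
detections `D`, fraction of detections matching no nucleus (`B/D`),
average undetected expected regions per nucleus (`U/N`), and average
detected regions per nucleus (`M/N`, with `M = D − B`).

## Synthetic scenes as the test bed

No public corpus accompanies the protocol this package implements, so a
first-class generator (`generateScene()`) produces liquid-based-cytology-like
fields with exact ground truth. Design:

* **Geometry.** Nuclei are rotated ellipses (semi-axes drawn uniformly
  from `nucleusRadiusRange`, default 9–16 px at the default 1024 × 1280
  field size); each sits inside a concentric cytoplasm ellipse scaled by
  `1/sqrt(NC)` with the N/C area ratio drawn from `ncRatioRange`
  (default 0.25–0.6). Placement is rejection sampling; with
  `overlapFraction = 0` (the default) whole-cell footprints are kept
  disjoint, mirroring the low-overlap character of liquid-based
  preparations. Overlapping placement is retained only as a stress knob;
  it is deliberately not part of any default because real overlapping
  smears are untested territory for the protocol.
* **Colour.** Colours are synthesised in HSV and converted to RGB. Blue
  nuclei draw hue from [0.58, 0.68] (inside the acceptance band
  [0.55, 0.72]), red nuclei from [0.02, 0.10]; nuclei are dark and
  saturated (S 0.55–0.85, V 0.35–0.55) while cytoplasm is pale
  (S 0.08–0.18, V 0.78–0.88) and the background is near-white. This makes
  "blue-stained" a *testable hue predicate* — the property the
  window-labelling rule and the reference detector both rely on. Debris
  blobs are small, grey-green and unsaturated, so they never enter the
  blue band.
* **Noise.** i.i.d. Gaussian noise (`stainNoiseSd`, default 0.015) on all
  RGB channels. Nucleus pixels differ from the background by far more
  than this, a generator invariant the tests assert.
* **Determinism.** A scene is a pure function of `(config, seed)`;
  regeneration is bit-exact. This allows memory-flat two-pass dataset
  assembly (enumerate labels, then re-generate and extract only sampled
  patches).

The stain parameter values above are the package's own realistic choices:
the underlying protocol never quantifies hue, cell density or noise. What
passing tests on these scenes demonstrate is that each pipeline stage is
*correct* (labelling rule, split arithmetic, matching, training
machinery) and that the detectors solve a cleanly separable version of
the task; they do not demonstrate accuracy on real smears, where chromatin
texture, focus variation, overlapping cells and staining variability are
all harder than anything the generator produces.

## The sliding-window dataset

* **Tiling** uses window = stride = 96 px; partial edge windows are
  dropped because the classifier input is fixed (padding would inject
  synthetic borders). A 1024 × 1280 field yields 10 × 13 = 130 windows.
* **Labelling rule.** A window is positive iff some *blue-lineage*
  nucleus has strictly more than half of its total mask area inside the
  window. The fraction is of the nucleus, not of the window, and the
  bound is strict: exactly 50 % coverage is negative. Red-lineage nuclei
  never label positive.
* **Balanced assembly** draws `nPerClass` windows per label without
  replacement (the canonical corpus is 394 + 394 = 788).
* **Split.** The stratified 3:1 split allocates
  `floor(trainFraction · N)` training slots overall and distributes them
  per label by largest-remainder apportionment (ties broken by label
  name). Plain per-label flooring would lose one sample at 394/394 ×
  0.75; apportionment reproduces the canonical 591/197 partition exactly
  while keeping each label's train fraction within `1/n` of the target.

## The patch classifier

The protocol describes the classifier only as stacks of convolution,
pooling, activation, dropout and affine layers with softmax output,
"18" or "24" layers deep, trained with categorical cross-entropy and
ADAM. The package pins down the open details as follows:

* **Layer counting.** Depth counts *every* convolution, activation,
  pooling, dropout, affine and softmax layer. Depth 18 is
  `[conv–act–pool] × 4` + dropout–affine–act–dropout–affine–softmax;
  depth 24 doubles the conv–act pairs in the first three blocks. Both
  reduce 96 → 6 px over four pooling stages.
* **Filters:** 8 → 16 → 32 → 32 with 3 × 3 kernels and same-padding,
  2 × 2 max pooling, a 64-unit hidden affine layer. These widths are
  deliberately modest so a full configuration-grid cell trains in
  minutes on one CPU core; the protocol never states filter counts.
* **Optimisation:** ADAM with step size 1e-3, β₁ = 0.9, β₂ = 0.999,
  batch size 32 (all unstated upstream, so package defaults), inverted
  dropout, He/Xavier initialisation matched to the activation, seeded
  end to end. Training histories are bit-reproducible for a fixed seed.
* **Engine.** Convolutions are computed as nine shifted-block GEMMs per
  layer, a pure-R formulation whose heavy lifting happens in BLAS; the
  backward pass is verified against numerical differentiation in the
  test suite. The first convolution skips its input gradient.
* **Accuracy accounting.** Reported train/test accuracy comes from full
  evaluation passes with dropout off; per-epoch history records the
  running training-mode figures plus a test-split evaluation.
* **Overlearning flag.** A grid cell is flagged when train accuracy
  exceeds test accuracy by more than `overfitGap = 0.05`, which
  separates a 99.8 %/89.1 % cell (flagged) from a 95.6 %/93.1 % cell
  (clean) — the calibration the four-criterion protocol implies.
* **Overlay semantics** are strict: `p > 0.9` red, `0.9 ≥ p > 0.5`
  yellow, otherwise untouched, so `p = 0.9` is yellow and `p = 0.5`
  untinted.

## Instance detection backends

The detection framework the instance side of the original protocol uses
(a two-stage region-proposal network) has no counterpart in this
package's dependency set, and re-deriving one is outside its scope.
`cytodetect` instead ships two backends behind one contract
(`DetectionSet`: scored masks filtered by `scoreThreshold` and greedy
mask-IoU NMS):

* **Hue-threshold reference detector** (`oracleDetect()`): pixels with
  hue in the blue band and saturation ≥ 0.3, 4-connected components of
  ≥ 20 px, score 1. On default synthetic scenes it is exact by
  construction (recall 1, zero background components) and therefore
  serves as the brute-force reference for every matching test.
* **Trainable pixel-classifier segmenter**
  (`trainInstanceSegmenter()` / `detectNuclei()`): a logistic colour
  model over per-pixel features (RGB, chroma, blueness `B − max(R,G)`,
  redness `R − max(G,B)`, `G − B`) fitted with ADAM on image + mask
  pairs, then thresholded at 0.5, connected components ≥ `minArea`,
  component score = mean pixel probability, NMS. Each epoch draws a
  balanced pixel sample per image whose background half is itself split
  between uniform pixels and strongly stained (high-chroma) pixels —
  red-lineage nuclei are rare by pixel count and would otherwise sit on
  the decision boundary. A fixed held-out pixel set tracks validation
  loss; the contract requires (and tests assert) a per-epoch history
  with final validation loss below the initial one.

The cytology-class tag on training pairs (`classTag`) is carried as
metadata only; detection uses a single "blue nucleus" foreground class.

## Matching and the four criteria

`matchDetections()` formalises what was originally a visual count:

* a detection matches a nucleus when
  `|det ∩ gt| / |det| ≥ 0.25` *or* the ground-truth centroid lies inside
  the detection mask (a permissive rule approximating human matching;
  strict IoU ≥ 0.5 is available via `criterion = "iou"`);
* every matched detection is assigned to its single best-overlapping
  nucleus, so `B + M = D` holds exactly;
* in **window mode** a nucleus's expected regions are its positively
  labelled grid windows and `U` counts expected windows missing from the
  detection set; in **instance mode** every nucleus is expected once.
  The sliding-window "detection" unit is any window with probability
  strictly above 0.5 — the lowest highlighted overlay band;
* `backgroundFraction = B/D` with the convention `0` when `D = 0`;
  averages are per ground-truth nucleus and require `N ≥ 1`;
* rounding is half-up (not banker's) at 4 decimals by default, matching
  how such report tables are conventionally printed.

## Problem sizes used by the tests and the acceptance script

The package's own desk-scale study conditions, stated once here:

* canonical window corpus: 40 fields of 512 × 640 px with 16 blue + 3
  red cells each → 788 balanced windows → 591/197 split;
* easy classifier corpus: 60 fields of 288 × 384 px (6 blue + 2 red),
  200 windows per class, the ReLU/20-epoch/depth-18/dropout-0.25
  configuration — the configuration the grid protocol singles out as
  best without overlearning;
* oracle fixed point: 100 fields of 192 × 256 px;
* matcher cross-validation: 200 randomised detection sets (oracle
  detections with random deletions plus stray boxes) against a
  full-raster all-pairs enumerator;
* backend comparison: 10 noisy evaluation fields (384 × 480 px, debris
  density 80/Mpx, noise sd 0.05) scored by both backends trained on the
  easy corpus. The comparison asserts direction only (instance ≤
  sliding-window on background fraction and undetected average), which
  is the qualitative conclusion the four-criterion protocol supports.

Full-size 1024 × 1280 defaults remain in `sceneConfig()` and
`runConfig()`; the sizes above keep the whole suite runnable in minutes
on a single core.

## Known limitations

* The generator has no chromatin texture, focus blur, scanner artifacts
  or cell clumping; classifier accuracies on it are upper bounds.
* The pixel segmenter is a colour model: it would not separate touching
  blue nuclei (excluded by the default generator) and has no notion of
  shape beyond the connected-component area gate.
* The Papanicolaou class (I–V) of a cell is metadata throughout;
  classifying atypia is explicitly out of scope.
* Reported depths (18/24) follow this package's counting convention;
  other conventions would count the same networks differently.
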
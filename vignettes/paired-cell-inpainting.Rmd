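---
title: "Self-supervised single-cell features by paired cell inpainting"
author: "cellInpaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised single-cell features by paired cell inpainting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-content fluorescence screens image thousands of proteins, each tagged in
its own strain or stained with its own antibody, together with structural
markers (a cytosolic RFP, a nuclear stain, microtubules) that are identical
across the whole collection. Quantitative analysis needs a feature vector per
single cell that is sensitive to the protein's subcellular localization but
robust to nuisance variation — illumination, focus, expression level,
cell-to-cell morphology. Hand-designed features and transfer-learned CNN
features both leave accuracy on the table, and supervised CNNs need
single-cell labels that rarely exist.

`cellInpaint` learns such features without any labels, by exploiting the one
piece of structure these collections always have: **all cells in one image
(one well) carry the same tagged protein and express it in a similar
pattern**.

## The pretext task

A single cell is a crop $c \in \mathbb{R}^{H \times W \times Z}$, split by
channel role into structural markers $x$ (channel set $Z_1$) and protein
channels $y$ (channel set $Z_2$). For a *source* cell $c_s$ and a *target*
cell $c_t$ drawn from the same image ($i_s = i_t$, $c_s \neq c_t$), the
network is trained to predict the target's protein channels from the
source's full channels plus the target's structural markers only:

$$\hat y_t = f(x_s, y_s, x_t), \qquad
  L(\hat y_t, y_t) = \frac{1}{h\,w} \sum_{h,w} (\hat y_t - y_t)^2 .$$

To succeed, the network must recognize the localization pattern in the
source cell and re-render it in the geometry of a different cell. Everything
specific to the source cell's own shape, intensity or illumination is
useless for the prediction, so the source-cell encoder is pushed toward
representations of the *pattern*, not the *instance* — and the target
markers hand the decoder the target's local illumination and morphology for
free, so the encoder does not have to carry nuisance at all. After training,
the prediction $\hat y_t$ is discarded; the source encoder becomes a feature
extractor.

Per epoch, every cell serves exactly once as a source; its target is drawn
uniformly from the other cells of the same image, and the pair order is
shuffled. Source and target cells are flipped horizontally/vertically as
augmentation, independently of each other, but a cell's marker and protein
channels always transform together.

## Architecture

The source cell encoder is an AlexNet-family stack: five 3×3
convolution blocks (batch normalization + ReLU) with 2×2 max-pooling after
blocks 1, 2 and 5. Default widths are the canonical AlexNet
96/256/384/384/256; all widths are configurable, and the benchmark profile
used throughout the tests is 16/32/32/32/32, which trains on one CPU in
minutes. The target marker encoder is smaller — three blocks of 16/32/32
filters, pooled after each — so both encoders bottom out at
$S/8 \times S/8$ for a crop of side $S$ and are concatenated along the
channel axis. The decoder reverses the encoder widths using
nearest-neighbour upsampling + convolution (transposed convolutions risk
checkerboard artifacts and nothing here requires them) and ends in a sigmoid
head: targets are min–max normalized to $[0,1]$, and a bounded output
stabilizes the squared loss. There are no skip connections. Convolutions are
stride 1 with size-preserving zero padding; all downsampling is pooling.
Training uses Adam at learning rate $10^{-4}$ for 30 epochs by default.

Implementation note: the numerical core (convolution as an offset-GEMM over
sample-interleaved panels, fused convolution–batchnorm–ReLU blocks, pooling
and upsampling, Adam) is compiled code under `src/`, verified against
central-difference gradients in the test suite.

Features are read from named taps `Conv1`..`Conv5` on the source encoder:
for each filter of the chosen layer, the maximum of the post-activation
feature map over spatial positions. Post-activation is a convention choice;
the tap location (rather than the bottleneck) follows the standard
layer-by-layer evaluation of self-supervised models, and the
`layerSweep()` report makes the choice empirical for any dataset. The
autoencoder baseline reuses the same source encoder and decoder to
reconstruct the input crop's own channels, with the target encoder unused —
features are then extracted identically.

## Preprocessing recipes

Two cropping recipes cover the field's two common situations:

* **center_based** ("yeast-style"): cell centers come from an external
  segmentation tool; a fixed crop (default 64 px) is cut around each center
  (half-open window, 0-based coordinates, zero padding at field borders —
  reflective padding would fabricate cell content). When segmentation mask
  areas are available, cells with a mask below 5% or above 95% of the crop
  area are discarded (inclusive bounds); images with fewer than 30 surviving
  cells are dropped.
* **otsu_nucleus** ("human-style"): the nuclear channel is binarized with an
  Otsu threshold; connected components under 400 px are discarded; a 512 px
  crop around each center of mass is resized bilinearly to 64 px (after a
  Gaussian antialias blur at $\sigma = \text{downscale}/2$); images with
  fewer than 5 cells are dropped.

Every crop is then min–max rescaled to $[0,1]$ per channel (channels have
unrelated dynamic ranges; a joint rescale would let a bright marker crush
the protein channel — the per-channel choice is a documented reading of an
ambiguous convention). Constant channels map to zero. In the human-style
recipe, structural-channel values below 0.05 are clipped to zero after
rescaling, following the recipe's stated order. Cells within an image are
ordered by (field, row, column) so cell ids are reproducible.

## What the synthetic generator emulates

`syntheticSpec()` describes a collection with the statistical structure the
pretext task assumes: many genetically identical cells per image sharing one
localization pattern; structural channel(s) common to the collection; a
protein channel whose pattern varies image to image. Cells are rotated
ellipses (12.5–13.5 px effective radius, axis ratio up to 1.4, nucleus
fraction 0.35–0.55 — large enough that a cell body always
exceeds the 400 px detection-area threshold, small enough that a cell fits
a 32 px crop) with a concentric elliptical nucleus. Six localization
classes are rendered geometrically: `nuclear`, `nucleolar` (1–3 foci inside
the nucleus), `nucleolar_rim`, `cytosolic`, `punctate` (Poisson-count foci
in the body), `membrane`, plus `mixture(classA,classB,alpha)` blending two
patterns.

Nuisance is chosen to put the benchmark in the regime real screens occupy —
hard enough that feature quality matters, while staying solvable:

* per-image gain $\sim U(0.7, 1.3)$ and a planar multiplicative
  illumination ramp (±15%) across the field, shared by all channels — the
  "local illumination" the target-marker input absorbs;
* per-image focus: Gaussian PSF with $\sigma \sim U(0.8, 1.6)$ px;
* per-image autofluorescence background $\sim U(0, 0.15)$;
* additive Gaussian noise, sd 0.12 on the $[0,1]$ scale;
* per-cell log-normal expression jitter (sd 0.4 — protein abundance varies
  several-fold between genetically identical cells) applied to the protein
  channel, with only mild variation on the structural stain, which is a
  dedicated bright marker;
* a per-cell *diffuse pool*: a fraction $\sim U(0.1, 0.4)$ of the protein
  signal is spread uniformly over the cell body rather than localized — the
  standard confound of GFP-tag and antibody images.

For mixture classes, each cell draws its own blend fraction from
$\mathrm{Beta}(\alpha\kappa, (1-\alpha)\kappa)$ with $\kappa = 8$: the mean
follows the image's $\alpha$, endpoints $\alpha \in \{0,1\}$ stay exactly
pure, and intermediate images show genuine cell-to-cell variability — the
phenomenon the variability screen is designed to detect.

What the generator does **not** model: optics beyond a Gaussian PSF,
cell-cycle dynamics, clumped or overlapping cells, segmentation artifacts,
low-penetrance patterns (e.g. mitotic figures) other than via the mixture
class, and the sheer pattern diversity of a proteome-scale screen. Passing
benchmarks on this generator therefore demonstrates that the machinery
learns and measures what it claims on data with the assumed structure — not
that a given accuracy will transfer to any particular real screen.

The ground-truth label, center and blend tables are written next to the
manifest but are never read by any training code path.

## Evaluation machinery

* `knnLooBalancedAccuracy()`: leave-one-out kNN (Euclidean, default
  $k = 11$) on standardized features; balanced accuracy is the unweighted
  mean of per-class recalls. Tie-breaks are deterministic (vote ties to the
  smallest sorted class name; distance ties by row index) — reproducibility
  is preferred over randomized ties. `layerSweep()` repeats this per tap
  layer with freshly extracted, freshly standardized features.
* `normalizedSameTermDistance()`: the mean cross-image cell distance for
  same-term image pairs, normalized against a different-term expectation as
  $(\bar d_\text{same} - \bar d_\text{diff}) / \bar d_\text{diff}$ (only
  the sign semantics are canonical; a z-score variant is available behind
  `normalization = "zscore"`). The balanced variant samples 1,000 same-term
  pairs per term and 1,000 pairs against each other term; the pooled
  variant reproduces the unbalanced 10,000-pair protocol with optional
  same/different cell-line constraints. Sampling uses a dedicated seed that
  is reported with the scores.
* `multilocScore()`: $\ln(d(\text{cell}, \bar f_A) / d(\text{cell},
  \bar f_B))$ against the mean feature vectors of two compartments;
  negative means closer to the first compartment. `variabilityStatistic()`
  ranks images by the population standard deviation of their cells' scores
  — a screen for single-cell variability.
* `hierarchicalCluster()`: agglomerative clustering of (protein-averaged)
  features on Euclidean distances. The linkage is configurable
  (`ward`, `average`, `complete`); Ward is the default because the
  literature this follows names no well-defined linkage, and Ward on
  standardized Euclidean spaces is the conservative default. Trees export
  to Newick.

Per-feature standardization fits on the full table (population sd;
zero-variance columns are centered and left unscaled) and returns the
fitted scaler so held-out data can reuse it.

## Numerical and design choices

* Seeds: one master seed derives independent streams for weight
  initialization, per-epoch pairing, and augmentation; identical seeds give
  identical training histories on a fixed BLAS.
* Batch statistics are used during training; running means/variances
  (momentum 0.1) at inference, so feature extraction is deterministic.
* The loss for one pair divides the summed squared error by $h \cdot w$
  only (summing over protein channels), exactly as defined; batches average
  per-pair losses.
* Degenerate inputs fail loudly as contract errors (mixed crop shapes,
  centers outside the field, non-finite features, single-row
  standardization), except where the recipes specify tolerance (constant
  channels normalize to zero; a constant detection channel warns and
  returns no centers; single-cell images contribute no pairs but are
  logged).
* Problem sizes in the shipped tests: the benchmark dataset is 6 classes ×
  30 images × 10–16 cells on 256×256 fields with 32 px crops and the
  16/32/32/32/32 width profile — chosen so a full
  simulate–crop–train–evaluate cycle runs on a single CPU in minutes while
  leaving every statistic estimable.

## Known limitations

* The pretext task needs ≥2 cells per image and cannot run on
  single-channel collections (no structural/protein split).
* Proteins whose localization is not predictable from cell structure
  (stochastic patterns) act as label noise in training; the loss then favors
  smoothed, averaged predictions.
* CPU-scale budgets (small widths, few epochs) leave the method's margin
  over baselines far smaller than at full scale; the benchmark checks
  ordering and sign properties, not absolute accuracies.
* The kNN protocol is a feature-set comparison device, not an optimized
  classifier.
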
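---
title: "Methods: from hyperspectral seed trays to per-seed reflectance and group calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from hyperspectral seed trays to per-seed reflectance and group calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seedhsi` processes line-scan hyperspectral images of seed trays end to end:
ENVI cube I/O, white/dark reflectance calibration, per-seed segmentation with
decomposition of touching seeds into ellipses, per-seed spectral extraction,
and a downstream analysis layer (seed- and pixel-level SVMs, a compact 3D
CNN, and split-count wavelength importance). This vignette documents the
models, the numerical choices, and what the synthetic test bed does and does
not establish.

## The imaging model

A line-scan spectrograph sweeps a tray and yields a hypercube indexed
(line *y*, sample *x*, band λ). The package fixes the internal axis order to
`(y, x, band)`; the on-disk interleave (BIL/BIP/BSQ) is purely a storage
concern resolved at read time. Band indices shown to users are 1-based, as
in ENVI headers and the instrument software; a typical cube is 640 samples
wide with 268 bands over 600–1700 nm.

Raw counts `Io` are converted to reflectance with the standard two-point
calibration against a white tile scan `Iw` and a capped-lens dark scan `Id`:

$$I_c = \frac{I_o - I_d}{I_w - I_d}$$

Reference cubes of any scan length are reduced to one (sample × band)
profile by averaging along the scan, the usual practice for line-scan rigs
whose reference tile fills the field of view. Cells where
`|Iw − Id| < eps` (default `1e-6`) are treated as dead: the output is 0
there and the count is reported, so a dead sensor column cannot poison seed
means. Reflectance is *not* clipped to [0, 1]; specular pixels can
legitimately exceed the white tile.

Sensor sensitivity collapses at the spectral extremes, so the band axis is
trimmed before analysis. The normative rule is the wavelength window
655–1642 nm (inclusive); on the standard 268-band grid this retains exactly
239 bands. A fraction-based mode (drop `ceiling(f·L)` bands per end,
default `f = 0.05`) exists but is off by default because the window rule is
what reproduces the 239-band convention exactly — symmetric 5% rounding
would give 240.

### Order of operations

Segmentation masks are computed from a **raw intensity** band slice; the
intensity window defaults (400, 2000) are on the camera's count scale and
would be meaningless on calibrated reflectance. Calibration and band
trimming then apply to the spectra that the masks extract. Within the
spectral path, the package calibrates first and trims second; the two
commute for the window rule, so this is a convention, not a modeling
choice.

## Segmentation

The chain is: strict intensity window `i_min < I < i_max` → 8-connected
component labeling → removal of components with fewer than `min_pixels`
pixels (strictly fewer: a component of exactly `min_pixels` survives) →
filling of fully enclosed holes → optional decomposition of merged
components into ellipses. Defaults: band 20, window (400, 2000),
`min_pixels = 500` at full instrument scale. Final seed labels are numbered
in reading order (top-most, then left-most bounding-box corner).

### Decomposing touching seeds

Touching seeds survive labeling as one component. Seeds are close to
elliptical, so the component is explained as a union of k ellipses with k
chosen automatically:

1. For each candidate k = 1..`max_ellipses` (default 6), fit a k-component
   full-covariance Gaussian mixture to the component's pixel coordinates by
   EM (relative log-likelihood tolerance 1e-4, at most 200 iterations).
   Initializations: a deterministic equal-count split along the component's
   principal axis — ideal for chains of touching ellipses — plus three
   seeded k-means++ restarts.
2. Convert each mixture component to an ellipse: the covariance contour
   scaled so its area matches the component's expected pixel share (for a
   uniformly filled ellipse the covariance eigenvalues are a²/4 and b²/4,
   so this recovers the axes). Using the soft EM means keeps centers of
   overlapping seeds unbiased.
3. Score each candidate by coverage: rasterize the union of its ellipses
   over the padded bounding box and count mismatched pixels against the
   actual region (a Bernoulli coverage log-likelihood up to scale), plus a
   per-ellipse penalty of 3% of the component area. The minimizing k wins.
4. Assign every pixel to the nearest ellipse in Mahalanobis distance (ties
   to the lower index), so sub-masks are disjoint and partition the
   component exactly.

Two design points deserve comment. First, the model-order score is
*coverage*, not the Gaussian mixture likelihood: uniformly filled ellipses
have lighter tails than Gaussians, so a likelihood criterion systematically
rewards splitting single seeds in two, while coverage only rewards a split
that actually explains area the single ellipse cannot. Second, the
per-ellipse penalty is proportional to component area (an extra ellipse
must explain at least ~3% of the region); a constant penalty cannot be
scale-free across seed sizes. The 3% constant was calibrated once on
development scenes spanning 0–25% overlap and is not exposed as a tuning
knob.

Known limitation: two seeds of similar width overlapping ~25% along a
common major axis form a union that is itself nearly elliptical. No
shape-only criterion can split such components reliably, and a minority of
them (roughly 1–2 seeds per 100 at 25% overlap in the synthetic bed) are
under-segmented. Sparser trays or lower overlap recover exactly.

## Extraction

Masks are applied across the full band axis. Each seed yields (a) a cropped
hypercube (bounding box, non-seed pixels zeroed, ENVI output) and (b) one
record of its band-wise mean spectrum with provenance (image id, seed
index, pixel count, centroid), written as CSV with one column per
wavelength (named by nm to two decimals, values at 8 significant digits —
round-trip error below 1e-6 relative). Existing outputs are skipped unless
overwriting is enabled.

## The synthetic test bed

`generate_scene()` renders what the acceptance suite measures against:

- a dark platform (background reflectance 0.05 over a dark level of 100
  counts against a white level of 3000, so background sits far below the
  default intensity window while seeds fall inside it);
- elliptical seeds (semi-axes 10–16 by 5–9 px at the default 200×200
  desk-scale frame, 60 bands over 600–1700 nm), placed separated or in
  pairs at a controlled overlap fraction of the smaller seed's area;
- two seed groups whose mean reflectance curves share the empirical
  structure of heat-stressed vs control seeds: the stressed curve sits at
  or above control everywhere, the two nearly coincide at 671–771 nm
  (|gap| < 0.01), and the gap opens to ≥ 0.03 beyond 1000 nm (peak 0.05).
  For importance studies the gap can instead be confined to a chosen
  window with raised-cosine tapers, exactly zero outside;
- independent additive Gaussian sensor noise (default sd 20 counts, i.e.
  ~0.7% of the reference range) on the scene and on full-frame white/dark
  reference scans, so that calibration recovers the planted curves in
  expectation.

Everything is reproducible bit-for-bit from one seed. What this bed does
*not* emulate: specularity, shadowing, the instrument point-spread
function, husk/chalkiness texture within a seed, and wavelength-dependent
lamp spectra. Passing tests therefore demonstrate the correctness of the
algorithms under their stated model, not performance on any particular real
instrument's output.

A subtlety worth recording: with short (few-line) reference scans, the
reference noise shared along each image column becomes a fixed-pattern
signal correlated with seed position, which is detectable by a flexible
classifier. The generator's references are full-frame scans, matching how
reference images are actually acquired; the closed-form standard error used
by the recovery tests carries both the per-pixel term and this
column-shared reference term with exact column weighting. Because ~120
per-band checks run simultaneously, the tests allow the multiplicity-
expected number of 3-SE exceedances (at most 2) with a hard 5-SE cap that
would catch any systematic bias.

## Classification

Group labels: heat-stress (`hs`) is the positive class.

- **Splits.** Seeds are split 80/20 stratified by group. The pixel-level
  test set is exactly the pixels of the test seeds; remaining pixels split
  95/5 into training and validation. No pixel crosses partitions.
- **Seed-level SVM.** PCA is fit on the training seeds' mean spectra only
  (centered on the training mean, unscaled — reflectance is already on a
  common scale); the top 50 components (capped by the data) feed an RBF
  SVM with C = 1 and γ = 1/(n_features · var). One seed is one sample, so
  seed-group prediction accuracy equals test accuracy.
- **Pixel-level SVM.** The same RBF SVM on single-pixel spectra, no
  spatial context. Pixel predictions are aggregated to seed calls by
  majority vote: a seed is control if strictly more than half its pixels
  are control, otherwise hs — an exact tie goes to hs, the literal
  complement of the strict-control rule.
- **3D CNN.** One training sample per seed pixel: the S×S spatial
  neighborhood with the full retained spectrum (S = 5; border patches are
  completed by edge-reflection padding so the one-sample-per-pixel count
  is exact). Architecture: C1 with two 3×3×7 kernels → ReLU → C2 with four
  3×3×7 kernels → ReLU → flatten → fully connected (width 128, ReLU) →
  linear → softmax over two classes; stride 1, no pooling — the smallest
  standard receptive field compatible with 5×5 patches. Training is SGD
  with momentum (lr 0.01, momentum 0.9, batch 128, ≤ 50 epochs) on the
  softmax cross-entropy, with validation-accuracy early stopping
  (patience 5) and the best validation weights retained. Inputs are
  z-scored with training statistics stored on the model; unscaled
  reflectance makes SGD with momentum overshoot into dead ReLUs. The
  network is implemented with im2col matrix multiplication (gradients are
  verified against numerical differentiation in the test suite) and is
  deterministic given its seed.
- **Metrics.** TP/TN/FP/FN with hs positive; accuracy, precision, recall
  and F = 2TP/(2TP+FP+FN), plus seed-group prediction accuracy after
  voting.

## Wavelength importance

Each wavelength is one feature of a gradient-boosted decision-tree
ensemble grown leaf-wise under a depth constraint (200 trees, 31 leaves,
depth ≤ 8, learning rate 0.1). Importance is the number of splits using a
wavelength divided by the total split count — a probability vector; ranks
sort importance descending with ties broken by ascending wavelength, and
the default report shows the top 12. Split counts, not gain, are the
primary metric; gain is available as an option.

Two properties of split-count importance matter in practice. At very high
signal-to-noise the ensemble separates the classes within its first trees
and the remaining trees accumulate splits on noise, diluting the signal
bands' share — the measure is most informative when noise is of the same
order as the group gap. And a wavelength the ensemble never split on has
zero importance by definition; reports and recovery checks only consider
bands that were actually used.

## Problem sizes used by the tests

The test and acceptance workloads run at desk scale, chosen as the
smallest sizes at which every recovery property is measurable: 200×200×60
scenes with 10 seeds for segmentation/extraction/importance (20 scenes for
count recovery, 10 replicates for importance), 280×280×60 with 20 seeds
for the three-classifier comparison (10 replicates), and a full-scale
640-sample, 268-band grid wherever only bookkeeping is exercised. The
"paper-scale" frame (640×1200×268) is supported by the same code paths via
`scene_spec()` but is not part of the routine suite.

## Known limitations

- Aligned high-overlap seed pairs can be under-segmented (see above).
- The CNN is a faithful but compact implementation; it targets desk-scale
  studies, not GPU-scale corpora.
- Wavelength importance attributes discriminative power, not biochemical
  meaning; relating bands to seed composition is out of scope.
- Vendor-native (non-ENVI) formats and streaming acquisition are not
  supported.
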
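---
title: "Semantic vegetation monitoring with svimon: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic vegetation monitoring with svimon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Fixed-point repeat photography programs collect ground-level RGB
photographs of the same landscape over years. Classic colour-threshold
vegetation indices computed on such images are fragile: they respond to
illumination, season, and camera as much as to vegetation itself. The
semantic alternative is to segment every pixel into land-cover classes
with a learned model and report the **Semantic Vegetation Index**,

$$\mathrm{SVI} = \frac{\sum_{i=1}^{n} SP_{a,i}}{\sum_{i=1}^{n} Area_{t,i}}
  \times 100\,\%$$

where $SP_{a,i}$ is the number of pixels classified as vegetation in
image $i$ and $Area_{t,i}$ its total pixel count. With one image per
index value this is simply the percentage of vegetation pixels. Site
series are the arithmetic means of per-image SVI within each calendar
quarter, plotted over years.

`svimon` implements that whole workflow: album generation (synthetic),
affine registration of repeat frames, dataset preparation, an
encoder–decoder segmentation network trained inside the package, the
standard evaluation metrics, and quarterly series aggregation, all
driven by one seeded configuration.

## Pipeline order and the registration model

Frames of an album are registered to the chronologically first frame of
their site *before* any resizing, then resized (default 256 px at full
scale, 64 px desk scale), then used for training or prediction.

Registration is classical and fully specifiable: Harris corners (with
sub-pixel quadratic refinement of the response peak), mean/contrast
normalized intensity patches as descriptors (sampled bilinearly; the
sensed side is described at scales 0.9/1.0/1.1 to tolerate moderate
zoom), mutual nearest-neighbour matching with a ratio test, RANSAC over
3-point minimal samples, and a least-squares refit over the consensus
set with one threshold-tightening pass. The estimated transform maps
sensed pixel coordinates (0-based, x = column) into the reference
frame. A Gauss–Newton photometric refinement stage was prototyped and
measurably *worsened* keypoint estimates on this imagery (its SSD
optimum is biased by seasonal appearance change), so it was dropped;
the keypoint path alone recovers random viewpoint jitters of up to 10
degrees, 10 % translation and ±10 % scale with a mean corner
reprojection error around 0.2–0.4 px on 128 px frames.

Registration of frames taken in *different* seasons is harder than
re-registering a jittered copy: vegetation boundaries genuinely move.
When fewer than six coherent inlier matches survive, `register_pair()`
raises a registration-failure error; the pipeline then logs a warning
and keeps the unregistered frame. This is safe for everything
downstream, because an unregistered frame's mask is still aligned with
its own pixels — registration normalizes viewpoint, it does not create
label consistency.

## The synthetic world

No public corpus of the original repeat-photography imagery exists, so
the package carries a first-class scene generator whose output is the
test bed for every downstream stage. A scene is a sky band above a
gently sinusoidal horizon, a textured terrain with scattered dark
rocks, and elliptical vegetation blobs in the conventional olive tone
(107, 142, 35), with per-blob colour jitter, per-image illumination
(±15 %), and Gaussian texture noise (default sd 8 of 255).

Two design points matter:

* **Persistent geometry.** A site's horizon, blob layout and rocks are
  drawn from a dedicated geometry seed that stays fixed across visits;
  only vegetation extent, photometry and viewpoint change. Repeat
  photographs of a site therefore actually depict one landscape, which
  is what makes cross-visit registration meaningful (static features —
  rocks, horizon — anchor the matches, exactly as in real imagery).
* **Exact ground truth.** Every non-sky pixel gets a normalized
  distance to its nearest blob; the `target` smallest distances become
  vegetation. The mask's vegetation count equals the requested fraction
  to the pixel, and growing the fraction grows the same blobs — a
  cheap, monotone model of seasonal green-up.

Seasonal dynamics follow
`clip01(base + amplitude * sin(2*pi*(q - phase)/4) + trend*(t - t0) + eps)`
with `eps ~ N(0, noise_sd)` per quarter. Defaults (base 0.3, amplitude
0.1, noise 0.02) give quarter-to-quarter swings of roughly ±10
percentage points of cover, a mid-latitude seasonal range.

What the generator does **not** emulate: perspective depth, occlusion,
shadows, species mixtures, non-rigid deformation, weather, and the
colour ambiguity of dry vegetation. A green test here establishes that
the machinery is correct and learnable on separable imagery — not that
field accuracy would match the published figures, which were obtained
on a real 3500-image corpus that is not deposited.

## The segmentation network

The segmenter is a U-Net: one 3×3 same-padded convolution + ReLU per
encoder level, 2×2 max pooling between levels, a bottleneck convolution
with dropout (default rate 0.5 in the full spec, 0.25 at desk scale;
training-time only), and a decoder that mirrors the encoder
level-for-level — nearest-neighbour 2× upsampling, concatenation of the
matching encoder features (the skip connection), and a 3×3 convolution
— finished by a 1×1 convolution and a per-pixel softmax over three
classes (other / vegetation / sky). `build_fcn()` is the identical
network without skip concatenations and serves as the comparison
baseline; its decoder must squeeze all spatial detail through the
bottleneck, which is precisely what the skip connections avoid, and the
test suite checks that the U-Net dominates it on accuracy and mIoU in
seeded repeats.

Because no deep-learning framework for R is available in the target
environment, the network is implemented natively: im2col/col2im in
C++ (Rcpp), convolutions as BLAS matrix products, hand-derived
backpropagation (verified against finite differences in the test
suite). The published source gives no layer counts or filter widths, so
depth and width are free parameters; the desk-scale default is depth 3,
16 base filters, which trains on 200 64-px scenes in a few minutes on
one CPU.

Training defaults follow the published configuration: batch 16,
learning rate 1e-4, categorical cross-entropy, SGD, up to 200 epochs.
Two recorded choices deserve a note. The configuration also names an
NMS threshold of 0.45 — an object-detection parameter with no semantics
in dense segmentation; it is stored in `train_config()` for fidelity
and never used. And SGD momentum is unspecified; the default here is
0.9. For the desk-scale runs in the acceptance battery the optimizer is
switched to Adam (2e-3) with 3–8 epochs — plain SGD at 1e-4 would need
hundreds of epochs at this scale, and the choice of optimizer is a
scaling decision, not part of the assessed contract. Early stopping
watches validation loss with patience 15 (desk scale: 6) and restores
the best-epoch weights. Argmax ties in prediction are broken toward the
lowest class id, making the untrained-uniform case deterministic.

## Evaluation conventions

Precision, recall, F1 and overall accuracy are computed from pixel
confusion counts with vegetation as the positive class —
vegetation-vs-rest binary, the only reading under which the published
formulas and the multi-class IoU table coexist. Aggregation over a test
set is micro (counts pooled before the formulas); the per-image overall
accuracies are reported alongside with their min/max, mirroring how
per-image spread is reported in the source. IoU is multi-class;
classes absent from both rasters are excluded from mIoU rather than
scored 1 or 0. Degenerate ratios (zero denominators) return 0 and are
flagged rather than silently propagating NaN.

## Numerical and format choices

* Rasters are stored as plain-text netpbm (ASCII PPM/PGM): the
  environment has no PNG reader for R, and text rasters are lossless
  and diffable. Masks may also be exchanged as colour images via
  `encode_mask_to_color()` / `decode_color_to_mask()` (strict mode
  rejects unknown colours by name; lenient mode snaps to the nearest
  colormap entry).
* Split sizes are `floor(frac * n)` for validation and test with the
  remainder to training — the only rounding rule that reproduces
  2800/525/175 at n = 3500 and keeps training largest for any n.
* Augmentation: flips and right-angle rotations are exact pixel
  permutations (and therefore conserve class counts and SVI exactly);
  zoom is a central crop in [0.8, 1) resized back; translation fills
  exposed borders with black/class "other"; Gaussian noise (sd 10) and
  blur (sigma 1.5) touch the image only. Augmentation is applied to
  the training partition only, after splitting — the source is silent
  on the order, and augmenting before splitting would leak augmented
  copies of one frame across partitions.
* Configuration files are a YAML subset (2-space indented key/value
  trees, scalars, comments) parsed in-package, or JSON; no external
  YAML parser exists in the target environment.
* One global seed derives all module seeds (`derive_seed`), each
  logged, so any stage can be re-run in isolation; results are
  reproducible bit-for-bit on a fixed platform.

## Known limitations

Cross-season registration of very small frames (64 px) fails in
roughly a third of attempts — too few stable corners survive — and the
pipeline's warn-and-continue fallback absorbs this. The network is a
desk-scale analogue, not the published GPU-scale model; its headline
numbers on synthetic scenes (pixel accuracy ≈ 0.99) say nothing about
field accuracy. The quarterly series reports raw means with explicit
gaps; no interpolation, smoothing or climate attribution is attempted.
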
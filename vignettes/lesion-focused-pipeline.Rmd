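---
title: "Methods: the lesion-focused fundus analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lesion-focused fundus analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`retifocus` implements a lesion-focused diagnosis pipeline for colour fundus
photographs. The idea: rather than feeding raw photographs to a
classification network, first segment the anatomical structures and lesions
that clinicians actually look at (optic cup and disc, macula, hemorrhages,
exudates, ...), then *composite* those segmentations back onto the
photograph as an attention signal — the blue channel is saturated wherever a
selected mask is foreground — and classify the composited image. The
attention steers the classifier toward diagnostically relevant pixels and
away from camera artefacts.

The package covers five stages, each usable on its own:

1. **Mask storage** (`encode_bitmap()` and friends): a bit-packed,
   PNG-backed format for up to 32 aligned binary masks.
2. **Lesion fusion** (`lesion_focused_image()`): the attention compositor.
3. **Models** (`build_retina_unet()`, `build_classifier()`): compact
   segmentation and classification networks with a self-contained CPU
   training engine.
4. **Evaluation** (`compute_roc()`, `stratify_by_median()`, ...): screening
   statistics and risk stratification.
5. **Synthetic data** (`generate_fundus()`, `generate_cohort()`): a fundus
   phantom generator so every stage is testable without clinical data.

# The BITMAP mask format

A lesion annotation is a stack of up to 32 aligned binary planes, one per
class in a fixed channel registry. The stack is bit-packed into a 4-channel
8-bit image: per pixel,

$$I_R = \sum_{i=0}^{7} 2^i\,m_i,\quad
  I_G = \sum_{i=8}^{15} 2^{i-8}\,m_i,\quad
  I_B = \sum_{i=16}^{23} 2^{i-16}\,m_i,\quad
  I_A = \sum_{i=24}^{31} 2^{i-24}\,m_i,$$

with plane $m_{8k}$ on the least significant bit of channel $k$. Decoding is
$m_i = \lfloor I_{\lfloor i/8\rfloor}/2^{i \bmod 8}\rfloor \bmod 2$. The
packed image is stored as a standard 8-bit RGBA PNG: no interlacing, default
zlib compression, alpha as data (never premultiplied). These choices make
the *channel values* bit-exact under round-trips; compressed byte streams
may differ across zlib builds, which is irrelevant to correctness. A
512×512×32 stack stored as raw 32-bit floats costs 32 MiB; an all-zero stack
in this format costs about 1 KB on disk.

Design choices worth stating:

* **Bit order.** The low/high-bit convention above is normative; it is
  validated by the round-trip identity property in the test suite.
* **Registry.** The canonical registry fixes 20 anatomy/lesion classes at
  channels 0–19 in the order of the packaged segmentation report (optic
  cup = 0 ... retinal detachment = 19). Channels 20–31 are reserved and must
  decode to all-zero planes. Absent classes are stored as zero planes rather
  than omitted, keeping the format fixed-width.
* **Aliases.** Clinical naming is not uniform; lookups accept documented
  alternate spellings ("optic disk", "tessellated retina", "atrophic
  crescent", "scleral show", ...). Two attention-set names with no exact
  counterpart among the 20 canonical classes are filed under their nearest
  neighbours: *preretinal fibrosis* under retinal neovascularization
  (fibrovascular proliferation) and *macular atrophy* under macular
  degeneration.

# Lesion fusion semantics

The compositor's contract, which this package treats as the normative
definition of a lesion-focused image:

1. A **fusion map** is the logical OR of the selected mask planes, scaled to
   {0, 255}. This is exactly a fixed-weight 3×1×1 convolution with zero
   weights on red/green and unit weight on blue, followed by threshold
   activation — we implement it directly as a bitwise operation.
2. A **field-of-view (FOV) mask** is obtained by thresholding the per-pixel
   maximum of R, G, B at `fov_threshold` (default 10 on the 8-bit scale),
   separating the retina from the black camera surround. Lesion pixels on
   the background are ignored.
3. The output has the original R and G planes unchanged; the blue plane is
   `(B AND NOT L) OR (255 AND L)` with `L = fusion AND FOV` — that is,
   saturated to 255 at lesion pixels and untouched elsewhere.

Two readings of the prose recipe were possible: zero the blue channel under
the lesion, or saturate it. Saturation is adopted — it preserves a strictly
brighter-than-anything-else attention cue and makes composition idempotent
(`compose(compose(x)) == compose(x)`), which the zeroing reading also
satisfies but with a weaker cue. "Bit-sum" is interpreted as saturating
bitwise OR and "reversed" as bitwise NOT on the binary map.

The **default attention set** follows the listed attention classes — optic
cup, optic disc, macula, hemorrhage, cotton wool spots, preretinal fibrosis,
atrophic arc, choroidal atrophy, choroidal neovascularization, exudation,
macular atrophy, and leopard/tessellated fundus — which resolves to 12
channels under the canonical registry. (The surrounding narrative calls this
set "nine anatomical structures and lesions" while listing twelve names; the
explicit list is taken as authoritative and the count discrepancy is noted,
not resolved.)

Because the same image is composited many times during training, the
generation function is wrapped in a cache keyed by (image id, registry
version, channel set, threshold). Equal keys return byte-identical images
without recomputation; an optional directory adds a PNG-backed persistent
layer whose file names are MD5 digests of the key.

# Segmentation: Retina-UNet

One *binary* network per class (no multi-class softmax head): small lesions
and large structures need separately tuned models, and per-class networks
keep the output contract trivial. The architecture is a U-shaped network
with a residual 18-layer encoder: at width multiplier 1 and input 256×256×3
the forward pass realises

    input 256×256×3 → stem 128×128×64 → pooled 64×64×64
      → encoder output 8×8×512
      → first decoder stage 16×16×256 → last decoder stage 256×256×16
      → head 256×256×1 (per-pixel probability)

with each encoder stage's feature map concatenated to the matching decoder
stage. The `width_multiplier` scales channel counts (`ceiling(base × m)`)
without touching spatial sizes, so the same contract is asserted at desk
scale.

Dataset **normalization** subtracts the per-channel mean of the training
image set and divides by the per-channel root mean square of the
mean-subtracted values (i.e. the population standard deviation; a reading
that divided by the *variance* would change units and is rejected). Both
statistics are kept at full double precision. Images are resized with
bilinear interpolation; masks with nearest-neighbour so labels stay binary.

Training choices (the procedure leaves them open; these are the package's):
pixel-wise binary cross-entropy plus a Dice term with equal weights — the
standard combination for heavily imbalanced binary segmentation; Adam with
learning rate 1e-3–5e-3; prediction binarisation at 0.5; a 4:1
patient-disjoint train/validation split (asserted, never assumed); early
stopping on validation loss; the best-validation-loss weights are returned.
Encoder weights are randomly initialised under a fixed seed — pretrained
initialisation is supported conceptually but never required by any test.

The per-class report score is the convex combination
`0.4 × IoU_train + 0.6 × IoU_val`, rounded to six decimals. The packaged
reference report (`inst/extdata/reference_iou_report.csv`) carries a
`consistent` flag: its *Retinal vessel* row duplicates the optic-disk row's
validation IoU and score, and its printed score cell cannot be reproduced
from its own IoU pair (0.899955 vs the printed 0.903637); the row is kept
as printed and flagged, not silently repaired.

# Classification: nine-stage MBConv network

The diagnosis network follows the familiar nine-stage
mobile-inverted-bottleneck design: stage 1 a standard 3×3 stride-2
convolution (batch norm + swish), stages 2–8 repeated MBConv blocks with
expansion factor 1 or 6 and kernels 3×3 or 5×5, and stage 9 a 1×1
convolution, global average pooling and a softmax head. Squeeze-excitation
is omitted at desk scale — it contributes a second-order refinement and
none of the package's architectural contracts depend on it. The head has
**five** outputs (GLAU, AMD, RVO, DR, NORM): one narrative passage mentions
a six-category variant, which we read as including an ungraded/other slot
and do not implement.

Training: patient-ID-disjoint 7:1:2 train/validation/test split (overlap is
a hard error), Adam, decoupled weight decay 1e-4 on convolution and dense
weights, softmax cross-entropy, seeded random horizontal flips (the one
augmentation that is label-preserving for fundus geometry), early stopping
with configurable patience, best-validation weights restored. Inputs are
scaled to [-1, 1]; the classifier's input size and width multiplier are
desk-scale dials — the architecture is exercised at multiplier 1 only in
shape tests.

**Grading** replaces the trained head with a 2-way (early/late) softmax and
fine-tunes from the diagnosis weights, inheriting learned fundus features.
Batch-norm running statistics are *re-estimated* on the grading cohort
rather than transferred: the base statistics describe the diseases task's
activation distribution, and carrying them over systematically degrades
early-epoch validation behaviour on the new task.
The package's transfer property — fine-tuning reaches a validation loss no
worse than training from scratch for the same number of epochs — is tested
across seeds rather than asserted per run, since at desk scale it is a
stochastic advantage.

# Evaluation statistics

* **ROC / AUC**: one operating point per distinct score plus endpoints;
  trapezoidal AUC, which equals the concordant-pair (rank) statistic with
  ties counted one half — asserted against an exhaustive pair oracle.
* **Operating threshold**: "both sensitivity and specificity maximized" is
  formalised as Youden's J = sens + spec − 1; ties break toward higher
  specificity (the hospital preference for fewer false positives).
  Screening and hospital modes are exposed as a policy flag that picks the
  lowest threshold with sensitivity ≥ 0.95 or the highest with
  specificity ≥ 0.95, respectively.
* **Byar approximation** for Poisson event-count CIs:
  `lower = x(1 − 1/(9x) − z/(3√x))³`,
  `upper = (x+1)(1 − 1/(9(x+1)) + z/(3√(x+1)))³`, `lower = 0` at `x = 0`.
  Cross-checked against exact Poisson quantile inversion (within 2%) and by
  Monte-Carlo coverage at λ = 20 (94–96%).
* **Odds ratio**: `(ad)/(bc)` with Haldane 0.5 added to all cells iff any
  cell is zero. The OR interval method is not pinned down by the source
  procedure; the Woolf log interval is adopted. No numeric OR target is
  taken from the reference risk table, whose printed counts are not
  internally reconcilable.
* **Bootstrap rate CIs**: percentile (2.5, 97.5) over 1,000 seeded
  resamplings.
* **Median split**: low = score < median, high = score ≥ median (ties to
  the high-risk group). The "positive rate" of a group is reported under
  both readings — within-group prevalence and share of all positives
  captured — explicitly labelled, since the reference table is ambiguous
  between them.
* The packaged confusion-count fixture flags the RVO row as internally
  inconsistent (its printed specificity/accuracy cannot be derived from its
  counts) and records that the DR row's positive/true-positive counts are
  transposed in the source narrative; the consistent rows are reproduced
  exactly.

# The synthetic generator

The generator emulates the gross structure of a fundus photograph: a
circular field of view on black background, a bright elliptical optic disc
with a brighter inner cup at a configurable cup-to-disc ratio, a darker
macula, and dark branching vessels random-walking outward from the disc
rim. Vessels emerge at the rim rather than the disc centre so the rendered
bright disc region stays consistent with the disc mask (a self-consistency
property the tests assert at IoU ≥ 0.9).

Disease signatures paraphrase clinical criteria: GLAU enlarges the cup to a
cup-to-disc ratio of 0.82 (early) or 0.92 (late); AMD places drusen and
exudate blobs within one disc diameter of the macula; RVO draws sectoral
flame hemorrhages radiating from the disc; DR scatters microaneurysm dots
and blob hemorrhages, adding exudates and neovessel streaks at the late
grade; NORM adds nothing. Grade controls lesion burden monotonically.
Signatures are deliberately strong — clearly separable geometry and
contrast — because the recovery experiments test the *pipeline*, not the
model's ability to detect borderline disease. A `render_lesions = FALSE`
mode writes signatures into the mask channels only, producing cohorts whose
class signal lives exclusively in the masks; this is the substrate for the
lesion-focused-vs-baseline comparison, where the raw-image baseline must
fall to chance.

What the generator does **not** emulate: photographic texture, optic-disc
vessel crossings, camera artefacts (overexposure, blur), inter-eye
laterality, or realistic lesion morphology. Passing recovery tests
therefore demonstrates that the machinery — formats, fusion, training
loops, statistics — is correct and end-to-end consistent; it says nothing
about clinical accuracy on real photographs, and the reference real-cohort
AUROC values (~0.99) are explicitly out of reach of synthetic data.

# Desk-scale problem sizes and numerics

The package's experiments are sized for a single CPU: cohorts of 100–125
patients (up to 500 images) at 96–128 px, classifiers at width multiplier
0.125–0.25 and input 64–96, segmentation at multiplier 0.25 and input 96,
ten to twenty training epochs. The full-width shape contract is asserted
with a single 256×256 forward pass. All randomness flows from explicit
seeds: weight initialisation from the model spec seed, batch shuffling and
splits from the training config seed, cohort geometry from the cohort seed.
Determinism is asserted by re-running training and comparing loss logs.

Numerical details: batch normalisation uses biased batch variance with
eps = 1e-5 and running statistics seeded from the first batch (important
for very short trainings); the softmax is computed with max-subtraction;
BCE uses eps = 1e-7 clamping; IoU of two empty masks is defined as 1; the
degenerate all-equal-scores ROC returns J = 0 with a warning rather than an
error.

# Known limitations

* The CPU engine is deliberately minimal: no SE blocks, no dropout, no
  augmentation beyond horizontal flips, no stochastic depth; at full width
  it is suitable for forward-pass contracts, not for training at scale.
* The fusion cache trusts its key; two producers that disagree for the same
  key are a caller error (the cache detects and repairs corrupt *files*,
  not wrong semantics).
* Output calibration by the variance ratio between model outputs and
  ground truth is referenced by the source procedure without an applicable
  formula; it is recorded here and not implemented.
* The synthetic generator's realism limits are described above; its
  defaults are the package's study conditions and are not tuned per test.
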
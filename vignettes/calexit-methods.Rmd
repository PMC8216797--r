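---
title: "Calibrated multi-exit classification: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated multi-exit classification: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calexit)
```

## The problem

Screening tasks such as urinary cytology ask a classifier two things at
once: be accurate on small-to-medium datasets (a few hundred labelled cell
images is typical), and be *calibrated* — when the model reports 80%
confidence it should be right about 80% of the time, because downstream
clinical decisions weigh the reported confidence, not just the predicted
label. Deep networks trained with plain cross-entropy are famously
miscalibrated: they are much more confident than they are accurate.

`calexit` implements a design that targets both goals jointly:

1. **early-exit auxiliary classifiers** attached to intermediate layers of a
   convolutional backbone, with a learned combination of all exits, to make
   better use of limited training data;
2. **focal-loss training** and **post-hoc temperature scaling** to keep the
   combined output calibrated;
3. a complete **calibration-evaluation suite** (binned ECE, reliability
   diagrams, confidence histograms, per-exit diagnostics).

## Model

The backbone is a VGG-style stack of macroblocks; block $b$ applies one or
more 3×3 "same" convolutions with ReLU and ends with a 2×2 max-pool.  For a
backbone with feature maps $h^i$, an auxiliary classifier (early exit)
attached after block $i$ produces

$$\hat f_i(x) = \mathrm{softmax}\,(c^i(h^i)),$$

where each $c^i$ is deliberately small: a flattening followed by a single
linear map to the $C$ class scores.  The backbone's own final classifier is
one more flatten+linear head on the last block, with parameters independent
of the last early exit (both heads read the same feature map; we keep both
because removing either changes the learned combination).  With $E$ heads,
a trainable weight vector $w \in \mathbb{R}^E$ forms the combined score
vector

$$t = \sum_{i=1}^{E} w_i\, \hat f_i(x), \qquad
  f(x) = \mathrm{softmax}(t),$$

and predictions are $\hat y = \arg\max_c f_c(x)$ with confidence
$\hat p = \max_c f_c(x)$.

**What the combiner sums.** Each head ends in a softmax (each head's output
enters a cross-entropy term during training, which expects a probability
vector), so the default combiner weighs *probability* vectors and $t$ is the
only pre-softmax quantity of the combined path.  Two alternatives are
available behind `backbone_config()` flags because the choice is genuinely
open: `combine_mode = "logits"` sums the heads' pre-softmax scores, and
`per_class_weights = TRUE` learns one weight per (head, class) pair,
$w \in \mathbb{R}^{E\times C}$.  The defaults are the literal reading of a
scalar weight per exit acting on the exit's published output.

**The single-head baseline.** `build_model(cfg, exit_after = integer(0))`
yields a plain CNN with one head.  For this degenerate case the combiner is
the identity on the head's *logits* ($t = c^E(h^E)$), not a weighted
probability vector: wrapping a probability vector in another softmax would
compress the baseline's confidences (a double softmax) and misrepresent the
calibration of exactly the model the multi-exit variants are compared
against.  A one-hot-weighted multi-exit model remains constructible for
verification, but the experiment grid's "standard" rows use the plain CNN.

**Initialisation.** Convolution kernels use fan-in-scaled normal draws
(variance $2/\text{fan-in}$, matching ReLU), heads variance $1/F$, combiner
weights $1/E$ so the ensemble starts uniform.  All initialisation is
seeded.

## Training objective

Per sample with true class $y$, writing $l$ for the per-sample loss,

$$\tilde l = \alpha\, l(y, f(x)) \;+\; \beta \sum_{i=1}^{E} l(y, \hat f_i(x)),$$

with $\alpha, \beta \ge 0$ (not both zero).  The $\beta$-sum runs over all
heads including the backbone's original classifier, but not the combined
output itself.  $\alpha = 0$ recovers deeply-supervised training;
$\beta = 0$ trains through the combiner alone.  Defaults are
$\alpha = \beta = 1$ (uniform balancing; a decaying per-exit schedule is out
of scope).  The minibatch objective is the mean of $\tilde l$.

The per-sample loss is either cross-entropy $-\log p_y$ or the focal loss

$$l_{\text{focal}} = -(1 - p_y)^{\gamma}\, \log p_y, \qquad \gamma \ge 0,$$

which damps the loss of samples the model already predicts confidently and
thereby discourages overconfidence; $\gamma = 0$ reproduces cross-entropy
exactly.  We use the conventional negative form (a loss must be bounded
below to be minimised).  Focal loss is equivalent to an entropy-regularised
objective — larger $\gamma$ pushes the predictive distribution towards
higher entropy — and the test suite checks exactly that qualitative
property on a trained model rather than asserting the bound as an equality.
The default $\gamma = 2$ is the common choice in the focal-loss literature;
`tune_gamma()` implements the validation-accuracy grid
$\gamma \in \{1, 2, 3\}$ for users who want the tuned variant (the
reference experiment uses the fixed default to keep the grid affordable).

Probabilities are floored at $10^{-12}$ inside every logarithm, so a
saturated softmax cannot produce an infinite loss or gradient.

## Calibration machinery

**Binning.**  Confidences partition $(0, 1]$ into $M$ equal bins
$((m-1)/M,\, m/M]$ (a confidence of exactly 0 joins bin 1; the convention
only matters for ties on bin edges).  Per nonempty bin we record size,
mean correctness and mean confidence; the expected calibration error is

$$\mathrm{ECE} = \sum_m \frac{B_m}{N}\,\bigl|\mathrm{acc}(B_m) -
\mathrm{conf}(B_m)\bigr|,$$

with empty bins contributing nothing (their accuracy/confidence are
reported as `NA`, not zero).  $M = 10$ throughout, the standard protocol.

**Temperature scaling.** After training, the combined scores are rescaled to
$\mathrm{softmax}(t/T)$ with a single scalar $T > 0$ fitted by minimising
the mean cross-entropy on the *validation* split (validation NLL, not focal
loss — fitting $T$ on the focal objective brings no benefit).  The search is
bounded scalar minimisation on $[0.05, 10]$ with tolerance $10^{-4}$; the
endpoints and $T = 1$ are always included as candidates, so the returned
temperature never has a worse NLL than the unscaled model.  Because
$t \mapsto t/T$ is order-preserving, accuracy is bit-identical before and
after scaling — the experiment report asserts this structural fact on every
variant.

**Per-exit diagnostics.** `per_exit_report()` evaluates each head in
isolation (accuracy and ECE of the head's own probabilities).  With TS
enabled, each head receives its *own* temperature fitted on validation data
(fitting on $\log \hat f_i$, which differs from the head's logits only by a
per-sample shift the softmax ignores); a single global temperature is
available behind `global_ts = TRUE`.  Per-head accuracy cannot change under
either mode — an order-preserving transformation cannot alter any argmax —
and the report asserts that invariance rather than emulating published
diagnostics in which TS appears to move per-exit accuracy.

## Data pipeline

Images are RGB in $[0,1]$, each carrying a class label and a patient
identifier.  The pipeline mirrors standard practice for small cytology
datasets:

1. **Centre four-crop** — the four quadrants meeting at the image centre,
   each $\lfloor H/2\rfloor \times \lfloor W/2\rfloor$; for even sizes they
   tile the image exactly, for odd sizes the centre row/column is dropped so
   the crops stay equal-sized (overlapping ceiling-sized corner crops are
   available behind `mode = "overlapping"`).  Each crop becomes its own
   sample and inherits label and patient.  Crops can optionally be
   bilinearly resized to the model input size.
2. **Patient-level 60/20/20 split** — patients (not images) are shuffled by
   a seeded RNG and allocated $\lfloor 0.6P\rfloor / \lfloor 0.2P\rfloor /
   \text{rest}$; every image follows its patient, so no patient's cells can
   leak across splits.  Fractions apply to patient counts because the exact
   image counts per split then depend on how many images each allocated
   patient has — the realistic situation.
3. **Rotation augmentation, training only** — each training crop is joined
   by its 90°/180°/270° rotations (exact array rotations, no resampling),
   quadrupling the training split while validation and test stay untouched.

No intensity normalisation beyond the $[0,1]$ scaling is applied.

## The synthetic cytology generator

Real urinary-cytology data is not redistributable, so the package ships a
generator that emulates the two morphological axes on which the Paris
system separates normal from atypical urothelial cells: the
nuclear-to-cytoplasmic (N/C) area ratio, with 0.5 as the clinical
threshold, and nuclear hyperchromasia (abnormally dark staining).  Each
image is a light tinted background, an elliptical cytoplasm (random area,
aspect, orientation, centre jitter) and a concentric nucleus ellipse whose
area is a class-dependent fraction of the cytoplasm; the nucleus intensity
is drawn from a class-dependent range.  Background tint and cytoplasm hue
are drawn per patient and shared across that patient's images, giving the
patient-level split something real to separate.  Gaussian pixel noise is
added and values are clipped to $[0,1]$.  Generation is a pure function of
`synth_params()` (bit-identical images for the same seed), and each image
records the areas of the masks actually rasterised so tests can re-measure
the morphology independently.

Default conditions: 40 patients × 20 images, balanced classes, N/C ranges
$(0.28, 0.47)$ vs $(0.53, 0.75)$ — adjacent to the 0.5 threshold, as the
clinical criterion implies — nucleus intensity $(0.28, 0.52)$ vs
$(0.12, 0.40)$ (overlapping: hyperchromasia is a tendency, not a rule),
noise SD 0.15, and 32 px source images (16 px crops).  These sizes put a
small CNN in a realistic 90–95% accuracy regime — hard enough that
architectural differences are visible, far from the ceiling — while keeping
a full experiment grid tractable on one CPU.  Real cytology crops are
typically 128 px; the morphology here is scale-free, so the smaller canvas
changes compute, not structure.

**What the generator does not emulate:** Papanicolaou stain chemistry,
out-of-focus regions, overlapping cell clusters, debris and inflammation,
scanner artefacts, or multi-grade labels.  Passing tests on this task
demonstrate that the architecture, losses, calibration machinery and
pipeline behave as specified — not that the model reaches any particular
accuracy on real cytology.

## The experiment grid

`run_grid()` crosses architecture (standard / multi-exit), training loss
(cross-entropy / focal) and temperature scaling (no / yes): eight variants,
in which TS rows reuse the non-TS checkpoint because TS is post-hoc.  Each
of the `n_runs` seeded runs re-randomises both the patient split and the
weight initialisation (run $r$ derives its seeds from `seed + r`;
`fix_split = TRUE` freezes the split instead), trains with Adam
(learning rate $10^{-3}$, minibatches of 32), and reports mean and SD of
test accuracy and test ECE per variant.  Early stopping monitors the
validation objective and restores the best-validation checkpoint.

`run_reference_experiment()` fixes the reference conditions used by the
acceptance script: the default generator above, a two-block backbone of
widths (8, 16) on 16 px crops, at most 10 epochs with patience 3, and 5
runs.  The epoch budget is deliberately small: the task converges in a
handful of epochs, and the grid (20 trained models) completes in minutes on
one CPU.  `directional_checks()` extracts the per-run qualitative
comparisons — multi-exit vs standard accuracy under both losses, ECE with
vs without TS for the multi-exit/focal model, and loss decrease over
epochs.

## Numerical conventions

- Argmax ties break towards the lowest class index, everywhere.
- Max-pool gradients route to the first maximum in a fixed window scan
  order, so training is deterministic under ties.
- Training is deterministic given the seed (single-threaded BLAS; the test
  suite asserts bit-level reproducibility of loss curves).
- The conv layers run as im2col + BLAS `dgemm` in compiled code
  (`src/nn_kernels.cpp`); gradients of every path are verified against
  central differences in the test suite.
- Checkpoints embed the backbone configuration and exit layout, so a saved
  model restores without side information.

**What the desk-scale experiment does and does not replicate.** On the
reference synthetic task the calibration findings replicate cleanly: the
training loss decreases, and temperature scaling improves the ECE of the
multi-exit focal model in every run (`directional_checks()` reports the
per-run outcomes, and the acceptance script reports the fractions).  The
*accuracy* advantage of the multi-exit architecture over the single-head
baseline, however, is not consistently observed here: at this scale the two
architectures are statistically indistinguishable (differences fall within
binomial noise on the test split), and the combiner converges to
down-weighting the shallow exit rather than extracting extra accuracy from
it.  That advantage is reported on real data in a genuinely small-data
regime — large-capacity backbones against a few thousand crops of a hard
task — whereas the synthetic task is data-rich relative to the small
reference backbone.  Users should read the grid's accuracy columns with
that in mind; the package replicates the mechanism, not the regime.

## Known limitations

- Heads are strictly flatten+linear; deeper auxiliary classifiers are not
  provided.
- Per-input adaptive exit selection (inference speed-up) is out of scope;
  all exits are always evaluated.
- The binning is fixed-width only; equal-mass binning and the
  histogram-binning / isotonic / Platt family of recalibrators are
  deliberately not implemented.
- The synthetic task, being two ellipses and noise, saturates quickly for
  wide class separations; the default parameters were chosen to avoid that
  regime, but conclusions about real staining variability require real
  data.
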
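# calexit

Calibrated multi-exit convolutional classifiers for cytology images, in R.

## The problem

Cell-image screening tasks — the motivating case is urinary cytology, where
urothelial cells are graded normal vs. atypical by nuclear-to-cytoplasmic
(N/C) ratio and nuclear hyperchromasia — come with small datasets and a
hard requirement that a classifier's *confidence* mean something: a
clinician acting on "95% malignant" needs that number to be calibrated, not
just the label to be right.  Plain CNNs trained with cross-entropy are
typically overconfident, and small datasets make both accuracy and
calibration worse.

`calexit` implements and evaluates a design that addresses both:

- a convolutional backbone with an **early-exit auxiliary classifier**
  (flatten + linear) after every pooling macroblock, and a trainable
  combination of all exits
  `t = Σᵢ wᵢ · f̂ᵢ(x)`, `f(x) = softmax(t)`;
- a **multi-exit objective**
  `α·l(y, f(x)) + β·Σᵢ l(y, f̂ᵢ(x))`
  where `l` is cross-entropy or the **focal loss**
  `−(1−p_y)^γ log p_y`;
- post-hoc **temperature scaling** `softmax(t/T)` with `T` fitted by
  validation NLL — order-preserving, hence accuracy-neutral;
- the standard **binned calibration suite**: expected calibration error
  `ECE = Σₘ (Bₘ/N)·|acc(Bₘ) − conf(Bₘ)|` over `M = 10` equal-width
  confidence bins, reliability diagrams, confidence histograms and
  per-exit diagnostics.

Because real cytology datasets are not redistributable, the package ships a
deterministic synthetic generator that emulates the two class-defining
morphological axes (N/C area ratio around the 0.5 clinical threshold, and
nucleus darkness), grouped by synthetic patients so that the leakage-free
patient-level 60/20/20 split has something real to do.  The full
preprocessing pipeline — centre four-crop, patient split, training-only
rotation augmentation — treats synthetic and real manifests identically.

## Worked example

Generate a synthetic cohort, split it by patient, run the preprocessing
pipeline, train a multi-exit model with the focal loss, and evaluate with
and without temperature scaling:

```r
library(calexit)

images   <- generate_synthetic_dataset(synth_params(seed = 1))
manifest <- patient_split(images, seed = 2)
splits   <- prepare_splits(images, manifest)     # 4-crop; train also 4x rotated

backbone <- backbone_config(block_channels = c(8, 16), convs_per_block = c(1, 1),
                            input_size = c(16, 16))
model    <- build_model(backbone, seed = 5)      # 2 early exits + original head

fit <- train_model(model, splits$train, splits$validation,
                   loss_config("focal", gamma = 2),
                   train_config(epochs = 10, early_stopping_patience = 3, seed = 11))

ev  <- evaluate(fit$model, splits$test)
evt <- evaluate(fit$model, splits$test, ts = TRUE, val_images = splits$validation)
cat(sprintf("accuracy %.4f | ECE %.4f -> with TS %.4f (T = %.2f)\n",
            ev$accuracy, ev$ece, evt$ece, evt$temperature))
```

```
accuracy 0.9359 | ECE 0.1341 -> with TS 0.0142 (T = 0.34)
```

The model is right on 93.6% of test crops; before scaling, its combined
output is badly *under*confident (the probability-weighted combiner
compresses scores, an ECE of 13.4%), and the fitted temperature `T < 1`
sharpens it to an ECE of 1.4% — at exactly the same accuracy, since
temperature scaling cannot change any argmax.  Per-head diagnostics come
from `per_exit_report(forward_with_exits(fit$model, ...), ...)`.

The eight-variant experiment (architecture × loss × TS, averaged over
seeded runs) is one call:

```r
report <- run_reference_experiment(seed = 1, progress = TRUE)
report$summary              # accuracy and ECE, mean ± SD per variant
directional_checks(report)  # per-run qualitative comparisons
make_report(report, "report-out")   # CSVs incl. diagram data
```

A thin command-line interface over the same functions ships at
`inst/cli/calexit.R` (subcommands `synth`, `train`, `evaluate`,
`calibrate`, `grid`, `report`).

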
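#' Training configuration
#'
#' @param learning_rate Adam learning rate (default `1e-3`).
#' @param batch_size Minibatch size (default 32).
#' @param epochs Maximum number of epochs.
#' @param n_runs Number of independent seeded runs for [run_grid()] (default
#'   5).
#' @param seed Master seed; run `r` uses seed `seed + r` for its split and
#'   weight initialisation.
#' @param early_stopping_patience Stop after this many epochs without
#'   improvement of the validation objective; the best-validation weights are
#'   restored.  `0` disables early stopping.
#' @return A `train_config` list.  The optimizer is Adam.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32, epochs = 50,
                         n_runs = 5, seed = 1, early_stopping_patience = 10) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, n_runs >= 1,
            early_stopping_patience >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_runs = as.integer(n_runs),
                 seed = as.integer(seed),
                 early_stopping_patience = as.integer(early_stopping_patience)),
            class = "train_config")
}

#' Train a multi-exit model
#'
#' Minimises the mean multi-exit objective with Adam over shuffled
#' minibatches.  After every epoch the validation objective is evaluated;
#' training stops early once it has not improved for
#' `early_stopping_patience` epochs, and the weights with the best
#' validation objective are returned.  Deterministic given
#' `train_cfg$seed`.
#'
#' @param model A `multiexit_model` (its current weights are the starting
#'   point).
#' @param train,validation Lists of `labeled_image` objects, or batch lists
#'   as produced by [images_to_batch()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @return A list with the trained `model` and a `history` data.frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(model, train, validation, loss_cfg, train_cfg) {
  tr <- if (is.list(train) && !is.null(train$x)) train else images_to_batch(train)
  va <- if (is.list(validation) && !is.null(validation$x)) validation else images_to_batch(validation)
  N <- dim(tr$x)[4L]
  if (N == 0L || dim(va$x)[4L] == 0L) {
    stop("train and validation splits must be nonempty", call. = FALSE)
  }
  bs <- min(train_cfg$batch_size, N)
  params <- model_params(model)
  state <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  patience <- train_cfg$early_stopping_patience
  withr::with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(N)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, N, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, N)]
        xb <- tr$x[, , , idx, drop = FALSE]
        out <- model_forward(model, xb, cache = TRUE)
        bk <- model_backward(model, out, tr$labels[idx], loss_cfg)
        if (!is.finite(bk$loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch),
               call. = FALSE)
        }
        upd <- adam_step(params, bk$grads, state, lr = train_cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        model <- model_set_params(model, params)
        epoch_loss <- epoch_loss + bk$loss
        n_batches <- n_batches + 1L
      }
      val_loss <- batch_objective(model_forward(model, va$x), va$labels, loss_cfg)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = epoch_loss / n_batches,
                                           val_loss = val_loss))
      if (val_loss < best$val - 1e-9) {
        best <- list(val = val_loss, params = params, epoch = epoch)
      } else if (patience > 0L && epoch - best$epoch >= patience) {
        break
      }
    }
  })
  list(model = model_set_params(model, best$params), history = history)
}

#' Evaluate a trained model on a split
#'
#' Computes accuracy and the binned expected calibration error of the
#' combined output.  With `ts = TRUE` a temperature is first fitted on the
#' validation combined scores (by validation NLL) and applied to the test
#' scores; accuracy is unchanged by construction since temperature scaling is
#' order-preserving.
#'
#' @param model A trained `multiexit_model`.
#' @param images Evaluation split (list of `labeled_image` or a batch list).
#' @param M Number of calibration bins.
#' @param ts Apply temperature scaling.
#' @param val_images Validation split, required when `ts = TRUE`.
#' @return A list: `accuracy`, `ece`, `table` (a [prediction_table()]),
#'   `temperature` (`NA` without TS).
#' @export
evaluate <- function(model, images, M = 10, ts = FALSE, val_images = NULL) {
  te <- if (is.list(images) && !is.null(images$x)) images else images_to_batch(images)
  if (dim(te$x)[4L] == 0L) stop("empty evaluation split", call. = FALSE)
  out <- model_forward(model, te$x)
  temp <- NA_real_
  if (ts) {
    if (is.null(val_images)) stop("ts = TRUE requires val_images", call. = FALSE)
    va <- if (is.list(val_images) && !is.null(val_images$x)) val_images else images_to_batch(val_images)
    vout <- model_forward(model, va$x)
    temp <- fit_temperature(t(vout$combined_scores), va$labels)
    probs <- temperature_scale(out$combined_scores, temp)
  } else {
    probs <- out$combined_probs
  }
  pred <- apply(probs, 2, which.max) - 1L
  tab <- prediction_table(labels = te$labels, confidence = apply(probs, 2, max),
                          predicted = pred)
  attr(tab, "scores") <- out$combined_scores
  list(accuracy = mean(pred == te$labels), ece = ece(tab, M), table = tab,
       temperature = temp)
}

#' The eight-variant experimental grid
#'
#' @return A data.frame crossing `architecture` (standard, multiexit), `loss`
#'   (cross_entropy, focal) and `ts` (FALSE, TRUE): 8 rows.
#' @export
variant_grid <- function() {
  expand.grid(architecture = c("standard", "multiexit"),
              loss = c("cross_entropy", "focal"),
              ts = c(FALSE, TRUE),
              stringsAsFactors = FALSE)
}

variant_key <- function(architecture, loss, ts) {
  paste(architecture, loss, ifelse(ts, "ts", "nots"), sep = "_")
}

#' Run the full experiment grid
#'
#' For each of `train_cfg$n_runs` seeded runs: split the dataset at the
#' patient level, run the preprocessing pipeline (four-crop everywhere,
#' rotation augmentation on training only), train one model per
#' (architecture, loss) pair, and evaluate each trained model with and
#' without temperature scaling — TS is post-hoc, so TS and non-TS rows share
#' one trained checkpoint and have identical accuracy.  The "standard"
#' architecture is a plain single-head CNN on the same backbone
#' (`exit_after = integer(0)`, combined-output loss only); "multiexit"
#' attaches an exit after every block and trains the full objective.
#' Results are averaged over runs.
#'
#' Seeds: run `r` uses `seed + r` for both the patient split and weight
#' initialisation (set `fix_split = TRUE` to reuse the split of run 1 across
#' runs and re-randomise only the weights).
#'
#' @param data A [synth_params()] object (the dataset is generated once) or a
#'   list of `labeled_image` objects.
#' @param backbone A [backbone_config()] whose input size matches the
#'   preprocessed crop size.
#' @param train_cfg A [train_config()].
#' @param gamma,alpha,beta Loss hyperparameters (see [loss_config()]).
#' @param variants Subset of [variant_grid()] to report.
#' @param resize_to Optional crop resize passed to [prepare_splits()].
#' @param fix_split Reuse one patient split across runs.
#' @param progress Print one line per trained model.
#' @return An `experiment_report`: `summary` (per-variant mean/SD of accuracy
#'   and ECE), `runs` (per run x variant), `history` (per-epoch losses),
#'   `tables` (last-run prediction tables per variant), `per_exit` (last-run
#'   per-head diagnostics of the multiexit models, without and with TS).
#' @export
run_grid <- function(data, backbone, train_cfg = train_config(),
                     gamma = 2, alpha = 1, beta = 1,
                     variants = variant_grid(), resize_to = NULL,
                     fix_split = FALSE, progress = FALSE) {
  if (nrow(variants) < 1L) stop("need at least one variant", call. = FALSE)
  images <- if (inherits(data, "synth_params")) generate_synthetic_dataset(data) else data
  arch_loss <- unique(variants[, c("architecture", "loss")])
  runs <- list(); hist <- list(); tables <- list(); per_exit <- list()
  for (r in seq_len(train_cfg$n_runs)) {
    run_seed <- train_cfg$seed + r
    split_seed <- if (fix_split) train_cfg$seed + 1L else run_seed
    manifest <- patient_split(images, seed = split_seed)
    splits <- prepare_splits(images, manifest, resize_to = resize_to)
    tr <- images_to_batch(splits$train)
    va <- images_to_batch(splits$validation)
    te <- images_to_batch(splits$test)
    for (k in seq_len(nrow(arch_loss))) {
      arch <- arch_loss$architecture[k]
      lk <- arch_loss$loss[k]
      exits <- if (arch == "multiexit") seq_along(backbone$block_channels) else integer(0)
      lcfg <- if (arch == "multiexit") {
        loss_config(lk, gamma = gamma, alpha = alpha, beta = beta)
      } else {
        loss_config(lk, gamma = gamma, alpha = 1, beta = 0)
      }
      model0 <- build_model(backbone, exit_after = exits, seed = run_seed * 8L + k)
      cfg_r <- train_cfg
      cfg_r$seed <- run_seed * 8L + 4L + k
      fit <- train_model(model0, tr, va, lcfg, cfg_r)
      if (progress) {
        message(sprintf("run %d %s/%s: %d epochs, best val %.4f",
                        r, arch, lk, nrow(fit$history), min(fit$history$val_loss)))
      }
      hist[[length(hist) + 1L]] <- cbind(run = r, architecture = arch,
                                         loss = lk, fit$history)
      for (use_ts in c(FALSE, TRUE)) {
        if (!any(variants$architecture == arch & variants$loss == lk &
                 variants$ts == use_ts)) next
        ev <- evaluate(fit$model, te, ts = use_ts, val_images = va)
        key <- variant_key(arch, lk, use_ts)
        runs[[length(runs) + 1L]] <- data.frame(
          run = r, seed = run_seed, architecture = arch, loss = lk,
          ts = use_ts, accuracy = ev$accuracy, ece = ev$ece,
          temperature = ev$temperature)
        tables[[key]] <- ev$table
      }
      if (arch == "multiexit") {
        te_out <- model_forward(fit$model, te$x)
        va_out <- model_forward(fit$model, va$x)
        pe <- rbind(
          cbind(ts = FALSE, per_exit_report(te_out, te$labels)),
          cbind(ts = TRUE, per_exit_report(te_out, te$labels, apply_ts = TRUE,
                                           val_outputs = va_out,
                                           val_labels = va$labels))
        )
        per_exit[[variant_key(arch, lk, FALSE)]] <- cbind(run = r, loss = lk, pe)
      }
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    rows <- runs[runs$architecture == v$architecture & runs$loss == v$loss &
                 runs$ts == v$ts, ]
    data.frame(architecture = v$architecture, loss = v$loss, ts = v$ts,
               acc_mean = mean(rows$accuracy), acc_sd = stats::sd(rows$accuracy),
               ece_mean = mean(rows$ece), ece_sd = stats::sd(rows$ece))
  }))
  structure(list(summary = summary, runs = runs,
                 history = do.call(rbind, hist), tables = tables,
                 per_exit = do.call(rbind, per_exit)),
            class = "experiment_report")
}

#' Per-run directional comparisons of an experiment report
#'
#' For every run of a completed grid, three qualitative checks of the
#' method's headline behaviour: (a) the multi-exit architecture is more
#' accurate than the standard one under both losses; (b) temperature scaling
#' does not worsen the ECE of the (multiexit, focal) model; (c) the training
#' loss of every trained model decreased from the first to the last epoch.
#'
#' @param report An `experiment_report` containing the full eight-variant
#'   grid.
#' @return A data.frame with one row per run and logical columns
#'   `acc_multiexit_gt_standard`, `ts_ece_not_worse`, `loss_decreased`.
#' @export
directional_checks <- function(report) {
  runs <- report$runs
  hist <- report$history
  get <- function(r, arch, lk, use_ts, col) {
    runs[runs$run == r & runs$architecture == arch & runs$loss == lk &
         runs$ts == use_ts, col]
  }
  out <- lapply(sort(unique(runs$run)), function(r) {
    acc_ok <- all(vapply(c("cross_entropy", "focal"), function(lk) {
      get(r, "multiexit", lk, FALSE, "accuracy") >
        get(r, "standard", lk, FALSE, "accuracy")
    }, logical(1)))
    ts_ok <- get(r, "multiexit", "focal", TRUE, "ece") <=
      get(r, "multiexit", "focal", FALSE, "ece")
    h <- hist[hist$run == r, ]
    dec_ok <- all(vapply(split(h, paste(h$architecture, h$loss)), function(g) {
      g$train_loss[nrow(g)] < g$train_loss[1L]
    }, logical(1)))
    data.frame(run = r, acc_multiexit_gt_standard = acc_ok,
               ts_ece_not_worse = ts_ok, loss_decreased = dec_ok)
  })
  do.call(rbind, out)
}

#' Write an experiment report to disk
#'
#' Emits `summary.csv` (the per-variant table), `runs.csv`,
#' `loss_curves.csv`, per-variant reliability-diagram and
#' confidence-histogram CSVs, and `per_exit.csv` when the report holds
#' multi-exit diagnostics.  All files round-trip through
#' [read_report_summary()] / `read.csv`.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if missing).
#' @param M Number of bins for the diagram data.
#' @return The directory, invisibly.
#' @export
make_report <- function(report, dir, M = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(report$history, file.path(dir, "loss_curves.csv"),
                   row.names = FALSE)
  for (key in names(report$tables)) {
    tab <- report$tables[[key]]
    bins <- bin_predictions(tab, M)
    utils::write.csv(reliability_diagram_data(bins),
                     file.path(dir, paste0("reliability_", key, ".csv")),
                     row.names = FALSE)
    ch <- confidence_histogram_data(tab, M)
    counts <- ch$counts
    counts$overall_accuracy <- ch$overall_accuracy
    counts$overall_confidence <- ch$overall_confidence
    utils::write.csv(counts,
                     file.path(dir, paste0("confidence_hist_", key, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$per_exit)) {
    utils::write.csv(report$per_exit, file.path(dir, "per_exit.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname make_report
#' @param dir Report directory written by [make_report()].
#' @export
read_report_summary <- function(dir) {
  utils::read.csv(file.path(dir, "summary.csv"))
}

#' Tune the focal-loss focusing parameter on validation accuracy
#'
#' Trains one model per candidate `gamma` and returns the value with the
#' highest validation accuracy (ties towards the smaller `gamma`).
#'
#' @param backbone A [backbone_config()].
#' @param train,validation Preprocessed splits (lists of `labeled_image` or
#'   batch lists).
#' @param train_cfg A [train_config()].
#' @param candidates Candidate `gamma` values.
#' @param alpha,beta Loss weights.
#' @param exit_after Exit layout for the tuned models.
#' @return A list: the selected `gamma` and the per-candidate validation
#'   accuracies.
#' @export
tune_gamma <- function(backbone, train, validation, train_cfg,
                       candidates = c(1, 2, 3), alpha = 1, beta = 1,
                       exit_after = seq_along(backbone$block_channels)) {
  va <- if (is.list(validation) && !is.null(validation$x)) validation else images_to_batch(validation)
  acc <- vapply(candidates, function(g) {
    m <- build_model(backbone, exit_after = exit_after, seed = train_cfg$seed)
    fit <- train_model(m, train, va, loss_config("focal", gamma = g,
                                                 alpha = alpha, beta = beta),
                       train_cfg)
    ev <- evaluate(fit$model, va)
    ev$accuracy
  }, numeric(1))
  list(gamma = candidates[which.max(acc)],
       accuracy = stats::setNames(acc, candidates))
}

#' Run the reference desk-scale experiment
#'
#' The package's canonical end-to-end experiment: the synthetic cytology task
#' at its default conditions (40 patients, 20 images each, 32 px images
#' yielding 16 px crops), a reduced two-block backbone (widths 8 and 16), and
#' the full eight-variant grid averaged over seeded runs.  Used by the
#' acceptance script and the worked examples; on one CPU a full 5-run grid
#' takes a few minutes.
#'
#' @param seed Master seed for splits and initialisation.
#' @param n_runs Number of independent runs (default 5).
#' @param epochs Maximum training epochs per model (default 10, early
#'   stopping patience 3).
#' @param progress Print per-model progress lines.
#' @return An `experiment_report` (see [run_grid()]).
#' @export
run_reference_experiment <- function(seed = 1, n_runs = 5, epochs = 10,
                                     progress = FALSE) {
  backbone <- backbone_config(c(8, 16), c(1, 1), input_size = c(16, 16))
  run_grid(synth_params(), backbone,
           train_config(epochs = epochs, early_stopping_patience = 3,
                        n_runs = n_runs, seed = seed),
           progress = progress)
}
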
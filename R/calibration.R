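#' Temperature-scaled softmax
#'
#' Divides pre-softmax scores by a scalar temperature `T` before the softmax:
#' `exp(t_c / T) / sum_j exp(t_j / T)`.  The transformation is monotone in
#' the scores, so the argmax (and hence every prediction) is unchanged for
#' any `T > 0`; only the sharpness of the distribution moves.
#'
#' @param scores Length-C score vector or `C x N` score matrix (one column
#'   per sample).
#' @param temperature Positive scalar `T`.
#' @return Probability vector / matrix of the same shape.
#' @examples
#' temperature_scale(c(2, 0), 2)  # softmax(c(1, 0))
#' @export
temperature_scale <- function(scores, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    stop("temperature must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("non-finite scores", call. = FALSE)
  if (is.matrix(scores)) {
    softmax_cols(scores / temperature)
  } else {
    drop(softmax_cols(matrix(scores / temperature, ncol = 1L)))
  }
}

nll_at_temperature <- function(scores, labels, temperature) {
  p <- temperature_scale(scores, temperature)
  sel <- cbind(as.integer(labels) + 1L, seq_len(ncol(p)))
  mean(-log(pmax(p[sel], 1e-12)))
}

#' Fit a temperature on validation scores
#'
#' Minimises the mean cross-entropy (negative log-likelihood) of the
#' temperature-scaled scores over `T` in `[0.05, 10]` by bounded scalar
#' minimisation (tolerance `1e-4`).  The returned temperature is guaranteed
#' to give an NLL no worse than `T = 1` (the unscaled model).
#'
#' @param scores `N x C` matrix of pre-softmax scores, one row per validation
#'   sample.
#' @param labels Zero-based true class indices, length N.
#' @param lower,upper Search interval for `T`.
#' @return The fitted temperature (positive scalar).
#' @export
fit_temperature <- function(scores, labels, lower = 0.05, upper = 10) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("empty validation set", call. = FALSE)
  if (nrow(scores) != length(labels)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  tz <- t(scores)
  obj <- function(T) nll_at_temperature(tz, labels, T)
  opt <- stats::optimize(obj, interval = c(lower, upper), tol = 1e-4)
  cand <- c(opt$minimum, 1, lower, upper)
  cand[which.min(vapply(cand, obj, numeric(1)))]
}

#' Assemble a prediction table
#'
#' The per-sample record that all calibration metrics consume: the
#' confidence (maximum combined probability), the predicted class and the
#' true class, optionally with the raw combined score vectors attached.
#'
#' @param outputs An `exit_outputs` object, or `NULL` when the three columns
#'   are given directly.
#' @param labels Zero-based true class indices.
#' @param confidence,predicted Optional explicit columns (used when
#'   `outputs` is `NULL`).
#' @param keep_scores Attach the `C x N` combined score matrix as an
#'   attribute.
#' @return A `prediction_table` data.frame with columns `sample_id`,
#'   `confidence`, `predicted`, `true`.
#' @export
prediction_table <- function(outputs = NULL, labels, confidence = NULL,
                             predicted = NULL, keep_scores = FALSE) {
  if (!is.null(outputs)) {
    stopifnot(inherits(outputs, "exit_outputs"))
    pr <- predict(outputs)
    confidence <- pr$confidence
    predicted <- pr$class
  }
  if (length(confidence) != length(labels) || length(predicted) != length(labels)) {
    stop("column lengths differ", call. = FALSE)
  }
  if (any(confidence < 0 | confidence > 1)) {
    stop("confidences must lie in [0, 1]", call. = FALSE)
  }
  tab <- data.frame(sample_id = seq_along(labels), confidence = confidence,
                    predicted = as.integer(predicted), true = as.integer(labels))
  if (keep_scores && !is.null(outputs)) {
    attr(tab, "scores") <- outputs$combined_scores
  }
  class(tab) <- c("prediction_table", "data.frame")
  tab
}

#' Bin predictions by confidence
#'
#' Partitions `(0, 1]` into `M` equal-width bins `((m-1)/M, m/M]`; a
#' confidence of exactly 0 goes to bin 1.  For each bin the size, the mean
#' correctness (accuracy) and the mean confidence are recorded; empty bins
#' carry `NA` accuracy/confidence and contribute nothing downstream.
#'
#' @param table A [prediction_table()].
#' @param M Number of bins (>= 1).
#' @return A `calibration_bins` data.frame with columns `bin`, `lower`,
#'   `upper`, `midpoint`, `count`, `accuracy`, `confidence`; the sample count
#'   `N` and `M` are attached as attributes.
#' @export
bin_predictions <- function(table, M = 10) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  conf <- table$confidence
  bin <- pmin(pmax(ceiling(conf * M), 1L), M)
  correct <- table$predicted == table$true
  count <- tabulate(bin, nbins = M)
  acc <- conf_mean <- rep(NA_real_, M)
  for (m in which(count > 0L)) {
    in_m <- bin == m
    acc[m] <- mean(correct[in_m])
    conf_mean[m] <- mean(conf[in_m])
  }
  out <- data.frame(bin = seq_len(M), lower = (seq_len(M) - 1) / M,
                    upper = seq_len(M) / M,
                    midpoint = (seq_len(M) - 0.5) / M,
                    count = count, accuracy = acc, confidence = conf_mean)
  attr(out, "N") <- nrow(table)
  attr(out, "M") <- M
  class(out) <- c("calibration_bins", "data.frame")
  out
}

#' Expected calibration error
#'
#' The bin-weighted mean absolute gap between per-bin accuracy and per-bin
#' confidence: `sum_m (B_m / N) * |acc(B_m) - conf(B_m)|` over nonempty
#' bins.
#'
#' @param bins A `calibration_bins` object from [bin_predictions()].
#' @param N Total sample count; defaults to the count recorded in `bins`.
#' @return ECE in `[0, 1]`.
#' @export
expected_calibration_error <- function(bins, N = attr(bins, "N")) {
  if (is.null(N) || N == 0) stop("N must be positive", call. = FALSE)
  ne <- bins$count > 0L
  sum(bins$count[ne] / N * abs(bins$accuracy[ne] - bins$confidence[ne]))
}

#' ECE straight from a prediction table
#'
#' Convenience composition of [bin_predictions()] and
#' [expected_calibration_error()].
#'
#' @inheritParams bin_predictions
#' @return ECE in `[0, 1]`.
#' @export
ece <- function(table, M = 10) {
  expected_calibration_error(bin_predictions(table, M))
}

#' Reliability-diagram data
#'
#' One record per nonempty bin: the bin midpoint, the mean confidence, the
#' mean accuracy and the gap `confidence - accuracy`.  A perfectly calibrated
#' model has all gaps zero (the diagonal of the diagram).
#'
#' @param bins A `calibration_bins` object.
#' @return A data.frame with columns `bin`, `midpoint`, `confidence`,
#'   `accuracy`, `gap`.
#' @export
reliability_diagram_data <- function(bins) {
  ne <- bins$count > 0L
  data.frame(bin = bins$bin[ne], midpoint = bins$midpoint[ne],
             confidence = bins$confidence[ne], accuracy = bins$accuracy[ne],
             gap = bins$confidence[ne] - bins$accuracy[ne])
}

#' Confidence-histogram data
#'
#' Per-bin counts of the maximum-probability confidence, together with the
#' overall mean accuracy and overall mean confidence (the two vertical lines
#' of the diagram; their agreement is a coarse calibration summary).
#'
#' @inheritParams bin_predictions
#' @return A list with `counts` (data.frame `bin`, `midpoint`, `count`),
#'   `overall_accuracy` and `overall_confidence`.
#' @export
confidence_histogram_data <- function(table, M = 10) {
  if (nrow(table) == 0L) stop("empty prediction table", call. = FALSE)
  bins <- bin_predictions(table, M)
  list(counts = data.frame(bin = bins$bin, midpoint = bins$midpoint,
                           count = bins$count),
       overall_accuracy = mean(table$predicted == table$true),
       overall_confidence = mean(table$confidence))
}

#' Per-exit accuracy and calibration report
#'
#' Evaluates every head of a multi-exit model in isolation: the accuracy and
#' ECE of each head's own probability vectors.  With `apply_ts = TRUE` a
#' separate temperature is fitted per head on validation data (on the log of
#' the head's probabilities, which differs from the head logits only by a
#' per-sample shift the softmax ignores) and applied before the ECE is
#' measured; per-head accuracy is unaffected because temperature scaling is
#' order-preserving.  `global_ts = TRUE` instead fits one temperature on the
#' combined validation scores and applies it to every head.
#'
#' @param outputs `exit_outputs` over the evaluation set.
#' @param labels Zero-based true classes for the evaluation set.
#' @param apply_ts Fit and apply temperatures before measuring ECE.
#' @param val_outputs,val_labels Validation outputs/labels, required when
#'   `apply_ts = TRUE`.
#' @param global_ts Use one shared temperature instead of per-head fits.
#' @param M Number of calibration bins.
#' @return A data.frame with one row per head: `exit`, `accuracy`, `ece`,
#'   `temperature` (`NA` without TS).
#' @export
per_exit_report <- function(outputs, labels, apply_ts = FALSE,
                            val_outputs = NULL, val_labels = NULL,
                            global_ts = FALSE, M = 10) {
  stopifnot(inherits(outputs, "exit_outputs"))
  if (length(labels) != outputs$n) stop("labels do not match outputs", call. = FALSE)
  if (apply_ts && (is.null(val_outputs) || is.null(val_labels))) {
    stop("validation outputs are required when apply_ts = TRUE", call. = FALSE)
  }
  E <- outputs$n_heads
  shared_T <- if (apply_ts && global_ts) {
    fit_temperature(t(val_outputs$combined_scores), val_labels)
  }
  rows <- lapply(seq_len(E), function(i) {
    p <- outputs$per_head_probs[[i]]
    temp <- NA_real_
    if (apply_ts) {
      temp <- if (global_ts) {
        shared_T
      } else {
        fit_temperature(t(log(pmax(val_outputs$per_head_probs[[i]], 1e-12))),
                        val_labels)
      }
      p <- temperature_scale(log(pmax(p, 1e-12)), temp)
    }
    pred <- apply(p, 2, which.max) - 1L
    tab <- prediction_table(labels = labels, confidence = apply(p, 2, max),
                            predicted = pred)
    data.frame(exit = i, accuracy = mean(pred == labels), ece = ece(tab, M),
               temperature = temp)
  })
  do.call(rbind, rows)
}

#' Read / write prediction tables as CSV
#'
#' Columns `sample_id`, `confidence`, `predicted`, `true`.
#'
#' @param table A [prediction_table()].
#' @param path CSV file path.
#' @return `write_prediction_table()` returns `path` invisibly;
#'   `read_prediction_table()` returns a `prediction_table`.
#' @export
write_prediction_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("sample_id", "confidence",
                                            "predicted", "true")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.csv(path)
  tab <- prediction_table(labels = df$true, confidence = df$confidence,
                          predicted = df$predicted)
  tab$sample_id <- df$sample_id
  tab
}
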
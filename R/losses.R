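#' Loss configuration for multi-exit training
#'
#' @param loss_kind `"cross_entropy"` or `"focal"`.
#' @param gamma Focusing parameter of the focal loss (>= 0); ignored for
#'   cross-entropy.  `gamma = 0` makes the focal loss identical to
#'   cross-entropy.
#' @param alpha Weight of the combined-output loss term (>= 0).
#' @param beta Weight of the summed per-exit loss terms (>= 0).  `alpha = 0`
#'   recovers purely deeply-supervised training; `beta = 0` trains the
#'   combined output alone.  Both zero is a configuration error.
#' @return A `loss_config` list.
#' @export
loss_config <- function(loss_kind = c("cross_entropy", "focal"), gamma = 2,
                        alpha = 1, beta = 1) {
  loss_kind <- match.arg(loss_kind)
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative", call. = FALSE)
  if (alpha == 0 && beta == 0) {
    stop("alpha and beta cannot both be zero", call. = FALSE)
  }
  structure(list(loss_kind = loss_kind, gamma = gamma, alpha = alpha,
                 beta = beta), class = "loss_config")
}

check_probs_label <- function(probs, label) {
  if (label < 0 || label >= length(probs) || label != floor(label)) {
    stop("label out of range [0, C)", call. = FALSE)
  }
}

#' Per-sample cross-entropy loss
#'
#' `-log(probs[label])`, with the probability floored at `1e-12` so saturated
#' softmax outputs cannot produce an infinite loss.
#'
#' @param probs Length-C probability vector.
#' @param label Zero-based true class index.
#' @return Nonnegative scalar loss.
#' @examples
#' cross_entropy_loss(c(0.5, 0.5), 0)  # 0.6931472
#' @export
cross_entropy_loss <- function(probs, label) {
  check_probs_label(probs, label)
  -log(max(probs[label + 1L], 1e-12))
}

#' Per-sample focal loss
#'
#' `-(1 - p)^gamma * log(p)` with `p = probs[label]`: cross-entropy damped by
#' the factor `(1 - p)^gamma`, which down-weights samples the model already
#' predicts confidently and thereby discourages overconfidence.  `gamma = 0`
#' reduces exactly to [cross_entropy_loss()].
#'
#' @inheritParams cross_entropy_loss
#' @param gamma Nonnegative focusing parameter.
#' @return Nonnegative scalar loss, always `<=` the cross-entropy of the same
#'   prediction.
#' @examples
#' focal_loss(c(0.5, 0.5), 0, gamma = 2)  # 0.25 * log(2)
#' @export
focal_loss <- function(probs, label, gamma) {
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  check_probs_label(probs, label)
  p <- max(probs[label + 1L], 1e-12)
  -(1 - p)^gamma * log(p)
}

per_sample_loss <- function(p, cfg) {
  p <- pmax(p, 1e-12)
  if (cfg$loss_kind == "focal") {
    -(1 - p)^cfg$gamma * log(p)
  } else {
    -log(p)
  }
}

#' Multi-exit training objective for one sample
#'
#' `alpha * l(y, combined) + beta * sum_i l(y, head_i)` where `l` is the
#' configured per-sample loss and the sum runs over all heads, including the
#' backbone's original classifier (the combined output itself is weighted by
#' `alpha` only).
#'
#' @param outputs An `exit_outputs` object holding exactly one sample.
#' @param label Zero-based true class index.
#' @param cfg A [loss_config()].
#' @return Nonnegative scalar loss.
#' @export
multiexit_loss <- function(outputs, label, cfg) {
  stopifnot(inherits(outputs, "exit_outputs"), outputs$n == 1L)
  check_probs_label(outputs$combined_probs[, 1L], label)
  head_sum <- sum(vapply(outputs$per_head_probs, function(p) {
    per_sample_loss(p[label + 1L, 1L], cfg)
  }, numeric(1)))
  cfg$alpha * per_sample_loss(outputs$combined_probs[label + 1L, 1L], cfg) +
    cfg$beta * head_sum
}

#' Mean multi-exit objective over a batch
#'
#' The minibatch estimate of the training cost: the arithmetic mean of
#' [multiexit_loss()] over the samples of a batch.
#'
#' @param outputs An `exit_outputs` object for the batch.
#' @param labels Zero-based true class indices, one per sample.
#' @param cfg A [loss_config()].
#' @return Nonnegative scalar.
#' @export
batch_objective <- function(outputs, labels, cfg) {
  stopifnot(inherits(outputs, "exit_outputs"))
  N <- outputs$n
  if (N == 0L) stop("empty batch", call. = FALSE)
  if (length(labels) != N) stop("labels do not match batch size", call. = FALSE)
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= outputs$num_classes)) {
    stop("label out of range [0, C)", call. = FALSE)
  }
  sel <- cbind(labels + 1L, seq_len(N))
  per <- cfg$alpha * per_sample_loss(outputs$combined_probs[sel], cfg)
  for (p in outputs$per_head_probs) {
    per <- per + cfg$beta * per_sample_loss(p[sel], cfg)
  }
  mean(per)
}
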
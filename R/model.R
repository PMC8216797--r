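#' Configure a convolutional backbone
#'
#' Describes a VGG-style backbone: a sequence of macroblocks, each a run of
#' 3x3 "same" convolutions with ReLU followed by a 2x2 max-pool.  Early-exit
#' heads attach to the pooled output of macroblocks (see [build_model()]).
#'
#' @param block_channels Integer vector, one entry per macroblock: the number
#'   of convolutional channels in that block.  At least two blocks are
#'   required (a single block makes a multi-exit model vacuous).
#' @param convs_per_block Integer vector of the same length: how many
#'   convolutional layers each block stacks before its pooling operation.
#' @param input_size Length-2 integer vector `c(height, width)` of the RGB
#'   input in pixels.  Each block halves the spatial size, so both dimensions
#'   must be divisible by `2^length(block_channels)`.
#' @param num_classes Number of output classes (>= 2).
#' @param combine_mode How the exit combiner aggregates heads: `"probs"`
#'   (default) takes the weighted sum of the per-head probability vectors;
#'   `"logits"` takes the weighted sum of the per-head pre-softmax scores.
#' @param per_class_weights If `TRUE`, the combiner learns one weight per
#'   (head, class) pair instead of one scalar per head.
#' @return A `backbone_config` list.
#' @examples
#' cfg <- backbone_config(c(8, 16), c(1, 1), input_size = c(16, 16))
#' @export
backbone_config <- function(block_channels, convs_per_block,
                            input_size = c(128, 128), num_classes = 2,
                            combine_mode = c("probs", "logits"),
                            per_class_weights = FALSE) {
  combine_mode <- match.arg(combine_mode)
  block_channels <- as.integer(block_channels)
  convs_per_block <- as.integer(convs_per_block)
  nb <- length(block_channels)
  if (nb < 2L) {
    stop("at least 2 macroblocks are required", call. = FALSE)
  }
  if (length(convs_per_block) != nb) {
    stop("convs_per_block must have one entry per macroblock", call. = FALSE)
  }
  if (any(block_channels < 1L) || any(convs_per_block < 1L)) {
    stop("channel widths and conv counts must be positive", call. = FALSE)
  }
  input_size <- as.integer(input_size[1:2])
  if (any(input_size %% 2L^nb != 0L)) {
    stop(sprintf("input size %dx%d is not divisible by 2^%d",
                 input_size[1], input_size[2], nb), call. = FALSE)
  }
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  structure(
    list(block_channels = block_channels, convs_per_block = convs_per_block,
         input_size = input_size, num_classes = num_classes,
         combine_mode = combine_mode, per_class_weights = per_class_weights),
    class = "backbone_config"
  )
}

#' A five-block preset mirroring the VGG-16 block layout
#'
#' Five macroblocks with the (2, 2, 3, 3, 3) convolution counts of VGG-16 but
#' reduced channel widths, on 128x128 inputs.  With the default exits of
#' [build_model()] this yields six heads: five early exits, one after each
#' pooling operation, plus the backbone's own final classifier.
#'
#' @param num_classes Number of output classes.
#' @param widths Channel widths per block.
#' @return A `backbone_config`.
#' @export
vgg_style_config <- function(num_classes = 2, widths = c(8, 16, 32, 32, 32)) {
  backbone_config(widths, c(2L, 2L, 3L, 3L, 3L),
                  input_size = c(128, 128), num_classes = num_classes)
}

# Flattened feature length at the pooled output of each block.
block_feature_dims <- function(config) {
  nb <- length(config$block_channels)
  h <- config$input_size[1] / 2L^seq_len(nb)
  w <- config$input_size[2] / 2L^seq_len(nb)
  as.integer(h * w * config$block_channels)
}

#' Build a multi-exit convolutional model
#'
#' Assembles the backbone described by `config`, attaches one flatten+linear
#' auxiliary classifier after the pooling operation of every block listed in
#' `exit_after`, and adds the backbone's own flatten+linear classifier on the
#' final block.  The model therefore has `E = length(exit_after) + 1` heads;
#' duplicate indices in `exit_after` are allowed and produce heads with
#' independent parameters (the final early exit and the original head
#' coexist on the last feature map in exactly this way).  A trainable
#' combiner weight vector `w`, initialised to `1/E`, balances the heads: the
#' combined score vector is `t = sum_i w_i * p_i` with `p_i` the head
#' probability vectors (or head logits under `combine_mode = "logits"`), and
#' the final prediction is `softmax(t)`.
#'
#' With `exit_after = integer(0)` the result is a plain single-head CNN: the
#' combiner is the identity and the combined scores are the head's logits.
#'
#' @param config A [backbone_config()].
#' @param exit_after Macroblock indices after which to attach early exits.
#'   Defaults to every block, the "exit after every pooling layer" layout.
#' @param seed Optional integer seed for weight initialisation.
#' @return A `multiexit_model` list with components `config`, `exit_after`,
#'   `conv` (convolution layers), `heads` (linear classifiers) and `w`.
#' @examples
#' m <- build_model(backbone_config(c(4, 8), c(1, 1), c(16, 16)), seed = 1)
#' length(m$heads)  # 3: two early exits + the original head
#' @export
build_model <- function(config, exit_after = seq_along(config$block_channels),
                       seed = NULL) {
  stopifnot(inherits(config, "backbone_config"))
  nb <- length(config$block_channels)
  exit_after <- as.integer(exit_after)
  if (length(exit_after) && (any(exit_after < 1L) || any(exit_after > nb))) {
    stop("exit index out of range for ", nb, " macroblocks", call. = FALSE)
  }
  init <- function() {
    C <- config$num_classes
    conv <- list()
    in_ch <- 3L
    for (b in seq_len(nb)) {
      for (k in seq_len(config$convs_per_block[b])) {
        out_ch <- config$block_channels[b]
        conv[[length(conv) + 1L]] <- list(
          W = array(stats::rnorm(9L * in_ch * out_ch, sd = sqrt(2 / (9 * in_ch))),
                    c(3L, 3L, in_ch, out_ch)),
          b = numeric(out_ch),
          block = b
        )
        in_ch <- out_ch
      }
    }
    feat <- block_feature_dims(config)
    head_blocks <- c(exit_after, nb)     # last entry is the original head
    heads <- lapply(head_blocks, function(b) {
      f <- feat[b]
      list(block = b,
           W = matrix(stats::rnorm(C * f, sd = sqrt(1 / f)), C, f),
           b = numeric(C))
    })
    E <- length(heads)
    w <- if (config$per_class_weights) {
      matrix(1 / E, E, C)
    } else {
      rep(1 / E, E)
    }
    structure(
      list(config = config, exit_after = exit_after, n_blocks = nb,
           conv = conv, heads = heads, w = w),
      class = "multiexit_model"
    )
  }
  if (is.null(seed)) init() else withr::with_seed(seed, init())
}

#' Total parameter count of the classification heads
#'
#' The heads are flatten+linear maps, so the count is the closed form
#' `sum_i (F_i + 1) * C` over heads with flattened feature length `F_i`.
#'
#' @param model A `multiexit_model`.
#' @return Integer parameter count.
#' @export
head_parameter_count <- function(model) {
  sum(vapply(model$heads, function(h) length(h$W) + length(h$b), numeric(1)))
}

as_image_batch <- function(x) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 4L || dim(x)[3L] != 3L) {
    stop("expected an H x W x 3 x N image batch", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite pixel values in input", call. = FALSE)
  x
}

# Full forward pass; with cache = TRUE retains the intermediates needed by
# model_backward().
model_forward <- function(model, x, cache = FALSE) {
  x <- as_image_batch(x)
  cfg <- model$config
  d <- dim(x)
  if (d[1L] != cfg$input_size[1] || d[2L] != cfg$input_size[2]) {
    stop(sprintf("batch spatial size %dx%d does not match configured %dx%d",
                 d[1L], d[2L], cfg$input_size[1], cfg$input_size[2]),
         call. = FALSE)
  }
  N <- d[4L]
  C <- cfg$num_classes
  pooled <- vector("list", model$n_blocks)
  conv_cache <- if (cache) vector("list", length(model$conv))
  pool_cache <- if (cache) vector("list", model$n_blocks)
  h <- x
  li <- 0L
  for (b in seq_len(model$n_blocks)) {
    for (k in seq_len(cfg$convs_per_block[b])) {
      li <- li + 1L
      cf <- conv3x3_forward(h, model$conv[[li]]$W, model$conv[[li]]$b)
      h <- relu(cf$out)
      if (cache) conv_cache[[li]] <- list(cols = cf$cols, in_dim = cf$in_dim, act = h)
    }
    pf <- maxpool2_forward(h)
    if (cache) pool_cache[[b]] <- pf
    h <- pf$out
    pooled[[b]] <- h
  }
  E <- length(model$heads)
  feats <- vector("list", E)
  scores <- vector("list", E)
  probs <- vector("list", E)
  for (i in seq_len(E)) {
    f <- matrix(pooled[[model$heads[[i]]$block]], ncol = N)
    z <- model$heads[[i]]$W %*% f + model$heads[[i]]$b
    feats[[i]] <- f
    scores[[i]] <- z
    probs[[i]] <- softmax_cols(z)
  }
  if (E == 1L) {
    t_mat <- scores[[1L]]
  } else {
    basis <- if (cfg$combine_mode == "probs") probs else scores
    t_mat <- matrix(0, C, N)
    for (i in seq_len(E)) {
      wi <- if (cfg$per_class_weights) model$w[i, ] else model$w[i]
      t_mat <- t_mat + wi * basis[[i]]
    }
  }
  out <- structure(
    list(per_head_probs = probs, per_head_scores = scores,
         combined_scores = t_mat, combined_probs = softmax_cols(t_mat),
         n_heads = E, num_classes = C, n = N),
    class = "exit_outputs"
  )
  if (cache) {
    attr(out, "cache") <- list(pooled = pooled, conv = conv_cache,
                               pool = pool_cache, feats = feats)
  }
  out
}

#' Forward pass through all exits
#'
#' Runs an image batch through the backbone, evaluates every head, and forms
#' the combined output.  Per-head probabilities are the softmax of each
#' head's linear scores; the combined scores are the combiner-weighted sum of
#' the heads and the combined probabilities their softmax.
#'
#' @param model A `multiexit_model` from [build_model()].
#' @param x An `H x W x 3` array or `H x W x 3 x N` batch with values in
#'   `[0, 1]`.
#' @return An `exit_outputs` object: lists `per_head_probs` and
#'   `per_head_scores` (each a `C x N` matrix per head), the `C x N`
#'   `combined_scores` and `combined_probs`, and the sizes `n_heads`,
#'   `num_classes`, `n`.
#' @export
forward_with_exits <- function(model, x) {
  model_forward(model, x, cache = FALSE)
}

#' Predicted class and confidence from exit outputs
#'
#' The predicted class is the argmax of the combined probabilities (ties
#' broken towards the lowest class index) and the confidence is the maximum
#' combined probability.
#'
#' @param object An `exit_outputs` object.
#' @param ... Unused.
#' @return A data.frame with zero-based `class` and `confidence` columns, one
#'   row per sample.
#' @export
predict.exit_outputs <- function(object, ...) {
  q <- object$combined_probs
  cls <- apply(q, 2, which.max) - 1L
  data.frame(class = as.integer(cls), confidence = apply(q, 2, max))
}

# ---- parameter flattening (training support) --------------------------------

# Combiner weights are trainable only for true multi-exit models.
combiner_trainable <- function(model) length(model$heads) > 1L

model_params <- function(model) {
  p <- list()
  for (l in model$conv) p <- c(p, list(l$W, l$b))
  for (h in model$heads) p <- c(p, list(h$W, h$b))
  if (combiner_trainable(model)) p <- c(p, list(model$w))
  p
}

model_set_params <- function(model, params) {
  i <- 0L
  for (k in seq_along(model$conv)) {
    model$conv[[k]]$W <- array(params[[i + 1L]], dim(model$conv[[k]]$W))
    model$conv[[k]]$b <- as.numeric(params[[i + 2L]])
    i <- i + 2L
  }
  for (k in seq_along(model$heads)) {
    model$heads[[k]]$W <- matrix(params[[i + 1L]], nrow(model$heads[[k]]$W))
    model$heads[[k]]$b <- as.numeric(params[[i + 2L]])
    i <- i + 2L
  }
  if (combiner_trainable(model)) {
    model$w <- if (is.matrix(model$w)) {
      matrix(params[[i + 1L]], nrow(model$w))
    } else {
      as.numeric(params[[i + 1L]])
    }
  }
  model
}

# Derivative of the per-sample loss w.r.t. the probability at the true class.
dloss_dp <- function(pl, kind, gamma) {
  pl <- pmin(pmax(pl, 1e-12), 1 - 1e-12)
  if (kind == "cross_entropy" || gamma == 0) {
    -1 / pl
  } else {
    gamma * (1 - pl)^(gamma - 1) * log(pl) - (1 - pl)^gamma / pl
  }
}

# Mean multi-exit objective over a cached forward pass, with gradients for
# every trainable parameter (same order as model_params()).
model_backward <- function(model, outputs, labels, loss_cfg) {
  cache <- attr(outputs, "cache")
  cfg <- model$config
  C <- cfg$num_classes
  N <- outputs$n
  E <- outputs$n_heads
  li <- as.integer(labels) + 1L
  sel <- cbind(li, seq_len(N))
  kind <- loss_cfg$loss_kind
  gamma <- loss_cfg$gamma %||% 0
  alpha <- loss_cfg$alpha
  beta <- loss_cfg$beta

  loss_val <- batch_objective(outputs, labels, loss_cfg)

  q <- outputs$combined_probs
  dheads_p <- lapply(seq_len(E), function(i) matrix(0, C, N))
  dz <- lapply(seq_len(E), function(i) matrix(0, C, N))
  dw <- if (combiner_trainable(model)) array(0, dim(model$w) %||% length(model$w))

  if (alpha > 0) {
    dq <- matrix(0, C, N)
    dq[sel] <- alpha / N * dloss_dp(q[sel], kind, gamma)
    dt <- softmax_backward_cols(q, dq)
    if (E == 1L) {
      dz[[1L]] <- dz[[1L]] + dt
    } else {
      basis <- if (cfg$combine_mode == "probs") outputs$per_head_probs else outputs$per_head_scores
      for (i in seq_len(E)) {
        if (cfg$per_class_weights) {
          dw[i, ] <- dw[i, ] + rowSums(dt * basis[[i]])
          contrib <- model$w[i, ] * dt
        } else {
          dw[i] <- dw[i] + sum(dt * basis[[i]])
          contrib <- model$w[i] * dt
        }
        if (cfg$combine_mode == "probs") {
          dheads_p[[i]] <- dheads_p[[i]] + contrib
        } else {
          dz[[i]] <- dz[[i]] + contrib
        }
      }
    }
  }
  if (beta > 0) {
    for (i in seq_len(E)) {
      p <- outputs$per_head_probs[[i]]
      dheads_p[[i]][sel] <- dheads_p[[i]][sel] + beta / N * dloss_dp(p[sel], kind, gamma)
    }
  }

  grads_conv <- vector("list", length(model$conv))
  dpooled <- lapply(cache$pooled, function(p) array(0, dim(p)))
  head_grads <- vector("list", E)
  for (i in seq_len(E)) {
    g <- dz[[i]] + softmax_backward_cols(outputs$per_head_probs[[i]], dheads_p[[i]])
    f <- cache$feats[[i]]
    head_grads[[i]] <- list(dW = g %*% t(f), db = rowSums(g))
    b <- model$heads[[i]]$block
    dpooled[[b]] <- dpooled[[b]] +
      array(crossprod(model$heads[[i]]$W, g), dim(cache$pooled[[b]]))
  }

  layer_of_block <- split(seq_along(model$conv),
                          vapply(model$conv, `[[`, numeric(1), "block"))
  dnext <- NULL
  for (b in rev(seq_len(model$n_blocks))) {
    g <- dpooled[[b]]
    if (!is.null(dnext)) g <- g + dnext
    g <- maxpool2_backward(g, cache$pool[[b]])
    for (l in rev(layer_of_block[[as.character(b)]])) {
      g <- g * (cache$conv[[l]]$act > 0)
      cb <- conv3x3_backward(g, cache$conv[[l]], model$conv[[l]]$W)
      grads_conv[[l]] <- list(dK = cb$dK, db = cb$db)
      g <- cb$dX
    }
    dnext <- g
  }

  grads <- list()
  for (l in seq_along(model$conv)) grads <- c(grads, list(grads_conv[[l]]$dK, grads_conv[[l]]$db))
  for (i in seq_len(E)) grads <- c(grads, list(head_grads[[i]]$dW, head_grads[[i]]$db))
  if (combiner_trainable(model)) grads <- c(grads, list(dw))
  list(loss = loss_val, grads = grads)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: the serialized object embeds the
#' [backbone_config()], the exit layout and a format tag alongside the
#' weights, so [load_model()] needs no side information.
#'
#' @param model A `multiexit_model`.
#' @param path File path for the checkpoint (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `multiexit_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "multiexit_model"))
  obj <- list(format = "calexit-checkpoint", format_version = 1L,
              config = unclass(model$config), exit_after = model$exit_after,
              weights = model_params(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "calexit-checkpoint")) {
    stop("not a calexit checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(backbone_config, obj$config[c("block_channels", "convs_per_block",
                                               "input_size", "num_classes",
                                               "combine_mode", "per_class_weights")])
  model <- build_model(cfg, exit_after = obj$exit_after, seed = 0L)
  model_set_params(model, obj$weights)
}
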
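# Independent oracles and small fixtures shared across the test files.

# Brute-force ECE: explicit double loop over bins and samples, no shared code
# with the package implementation.
brute_force_ece <- function(conf, correct, M) {
  N <- length(conf)
  total <- 0
  for (m in seq_len(M)) {
    lo <- (m - 1) / M
    hi <- m / M
    members <- integer(0)
    for (i in seq_len(N)) {
      if ((conf[i] > lo && conf[i] <= hi) || (m == 1L && conf[i] == 0)) {
        members <- c(members, i)
      }
    }
    if (length(members) > 0L) {
      total <- total + length(members) / N *
        abs(mean(correct[members]) - mean(conf[members]))
    }
  }
  total
}

random_prediction_table <- function(n, C = 4L) {
  prediction_table(labels = sample(0:(C - 1L), n, replace = TRUE),
                   confidence = stats::runif(n),
                   predicted = sample(0:(C - 1L), n, replace = TRUE))
}

# Grid-search oracle for the temperature fit.
grid_search_temperature <- function(scores, labels, grid = seq(0.1, 10, by = 0.1)) {
  nll <- vapply(grid, function(T) {
    p <- temperature_scale(t(as.matrix(scores)) / 1, T)  # C x N
    sel <- cbind(as.integer(labels) + 1L, seq_len(ncol(p)))
    mean(-log(pmax(p[sel], 1e-12)))
  }, numeric(1))
  grid[which.min(nll)]
}

# Direct sextuple-loop 3x3 "same" convolution.
naive_conv3x3 <- function(X, K, b) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(K)[4]
  out <- array(0, c(H, W, Cout, N))
  for (n in seq_len(N)) for (co in seq_len(Cout)) for (w in seq_len(W)) for (h in seq_len(H)) {
    s <- b[co]
    for (ci in seq_len(Cin)) for (dx in -1:1) for (dy in -1:1) {
      hh <- h + dy; ww <- w + dx
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
        s <- s + K[dy + 2, dx + 2, ci, co] * X[hh, ww, ci, n]
      }
    }
    out[h, w, co, n] <- s
  }
  out
}

# Scores drawn so that softmax(z) is exactly the label-generating
# distribution (a calibrated scorer), then inflated by `c`.
calibrated_scores <- function(n, C = 2L, inflate = 1) {
  z <- matrix(stats::rnorm(n * C, sd = 1.5), n, C)
  p <- exp(z) / rowSums(exp(z))
  labels <- vapply(seq_len(n), function(i) sample(0:(C - 1L), 1L, prob = p[i, ]),
                   integer(1))
  list(scores = z * inflate, labels = labels)
}

tiny_backbone <- function(...) {
  backbone_config(c(4, 8), c(1, 1), input_size = c(8, 8), ...)
}

# A small synthetic dataset at 16 px (8 px crops) for fast training tests.
tiny_dataset <- function(n_patients = 8, images_per_patient = 6, seed = 3) {
  generate_synthetic_dataset(synth_params(n_patients = n_patients,
                                          images_per_patient = images_per_patient,
                                          image_size = 16, seed = seed))
}

make_tiny_splits <- function(seed = 3) {
  imgs <- tiny_dataset(seed = seed)
  man <- patient_split(imgs, seed = seed)
  prepare_splits(imgs, man)
}

fake_outputs <- function(per_head_probs, combined_probs) {
  structure(list(per_head_probs = per_head_probs,
                 per_head_scores = lapply(per_head_probs, log),
                 combined_scores = log(combined_probs),
                 combined_probs = combined_probs,
                 n_heads = length(per_head_probs),
                 num_classes = nrow(combined_probs),
                 n = ncol(combined_probs)),
            class = "exit_outputs")
}
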
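test_that("temperature scaling matches hand-evaluated cases and preserves order", {
  z <- c(1.2, -0.3, 0.5)
  expect_equal(temperature_scale(z, 1), exp(z) / sum(exp(z)), tolerance = 1e-12)
  expect_equal(temperature_scale(c(2, 0), 1e6), c(0.5, 0.5), tolerance = 1e-5)
  expect_equal(temperature_scale(c(2, 0), 2),
               c(0.731059, 0.268941), tolerance = 1e-6)
  set.seed(3)
  for (T in c(0.1, 0.7, 3, 9)) {
    zz <- rnorm(5)
    expect_equal(which.max(temperature_scale(zz, T)), which.max(zz))
  }
  expect_error(temperature_scale(c(1, 0), 0), "positive")
  expect_error(temperature_scale(c(1, 0), -2), "positive")
})

test_that("the fitted temperature matches a grid-search oracle", {
  set.seed(14)
  cs <- calibrated_scores(1500, C = 3, inflate = 5)   # overconfident by 5x
  T_fit <- fit_temperature(cs$scores, cs$labels)
  expect_gt(T_fit, 1)
  T_grid <- grid_search_temperature(cs$scores, cs$labels)
  expect_equal(T_fit, T_grid, tolerance = 0.1)
  # NLL at the fit never exceeds NLL at T = 1
  ns <- asNamespace("calexit")
  expect_lte(ns$nll_at_temperature(t(cs$scores), cs$labels, T_fit),
             ns$nll_at_temperature(t(cs$scores), cs$labels, 1) + 1e-8)
  # fixed point: rescaling by the fitted temperature refits to ~1
  T_refit <- fit_temperature(cs$scores / T_fit, cs$labels)
  expect_equal(T_refit, 1, tolerance = 0.05)
  expect_error(fit_temperature(matrix(numeric(0), 0, 2), integer(0)), "empty")
})

test_that("temperature fitting recovers a known inflation factor", {
  set.seed(31)
  cs <- calibrated_scores(4000, C = 2, inflate = 3)
  T_fit <- fit_temperature(cs$scores, cs$labels)
  expect_equal(T_fit, 3, tolerance = 0.2 * 3)
})

test_that("binning follows the left-open right-closed convention", {
  tab <- prediction_table(labels = c(0, 1, 0, 0),
                          confidence = c(0.95, 0.95, 0.65, 0.65),
                          predicted = c(0, 0, 0, 0))
  bins <- bin_predictions(tab, M = 10)
  expect_equal(bins$count[10], 2)
  expect_equal(bins$accuracy[10], 0.5)
  expect_equal(bins$confidence[10], 0.95)
  expect_equal(bins$count[7], 2)
  expect_equal(bins$accuracy[7], 1.0)
  expect_equal(bins$confidence[7], 0.65)
  expect_equal(sum(bins$count), 4)
  # a confidence of exactly zero falls in bin 1; bin edges are (.,  ]
  edge <- prediction_table(labels = c(0, 0, 0), confidence = c(0, 0.1, 0.1000001),
                           predicted = c(0, 0, 0))
  eb <- bin_predictions(edge, 10)
  expect_equal(eb$count[1], 2)
  expect_equal(eb$count[2], 1)
  expect_error(bin_predictions(tab, 0), "M must be")
  # partition property on random tables
  set.seed(2)
  for (r in 1:5) {
    rt <- random_prediction_table(137)
    expect_equal(sum(bin_predictions(rt, sample(1:20, 1))$count), 137)
  }
})

test_that("ECE reproduces the hand-binned example and stays in [0, 1]", {
  tab <- prediction_table(labels = c(0, 1, 0, 0),
                          confidence = c(0.95, 0.95, 0.65, 0.65),
                          predicted = c(0, 0, 0, 0))
  expect_equal(ece(tab, 10), 0.5 * 0.45 + 0.5 * 0.35, tolerance = 1e-12)
  expect_equal(ece(tab, 10), 0.40, tolerance = 1e-12)
  perfect <- prediction_table(labels = rep(0, 5), confidence = rep(1, 5),
                              predicted = rep(0, 5))
  expect_equal(ece(perfect, 10), 0)
  set.seed(7)
  for (r in 1:20) {
    rt <- random_prediction_table(211)
    e <- ece(rt, 10)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("binned ECE agrees with the brute-force double loop", {
  set.seed(19)
  for (r in 1:50) {
    rt <- random_prediction_table(sample(50:400, 1))
    M <- sample(c(5, 10, 15), 1)
    expect_equal(expected_calibration_error(bin_predictions(rt, M)),
                 brute_force_ece(rt$confidence, rt$predicted == rt$true, M),
                 tolerance = 1e-9)
  }
})

test_that("a calibrated confidence generator drives ECE towards zero", {
  set.seed(23)
  n <- 20000
  conf <- stats::runif(n, 0.5, 1)
  correct <- stats::rbinom(n, 1, conf)
  tab <- prediction_table(labels = ifelse(correct == 1, 0, 1),
                          confidence = conf, predicted = rep(0, n))
  expect_lt(ece(tab, 10), 0.02)
})

test_that("reliability-diagram records carry the per-bin gaps", {
  tab <- prediction_table(labels = c(0, 1, 0, 0),
                          confidence = c(0.95, 0.95, 0.65, 0.65),
                          predicted = c(0, 0, 0, 0))
  rd <- reliability_diagram_data(bin_predictions(tab, 10))
  expect_equal(nrow(rd), 2)
  expect_equal(rd$gap[rd$bin == 10], 0.45, tolerance = 1e-12)
  expect_equal(rd$gap[rd$bin == 7], -0.35, tolerance = 1e-12)
  expect_true(all(rd$gap >= -1 & rd$gap <= 1))
  perfect <- prediction_table(labels = rep(0, 8), confidence = rep(1, 8),
                              predicted = rep(0, 8))
  expect_true(all(reliability_diagram_data(bin_predictions(perfect, 10))$gap == 0))
})

test_that("confidence histograms report counts and overall summary lines", {
  tab <- prediction_table(labels = c(0, 1, 0, 0),
                          confidence = c(0.95, 0.95, 0.65, 0.65),
                          predicted = c(0, 0, 0, 0))
  ch <- confidence_histogram_data(tab, 10)
  expect_equal(ch$counts$count[ch$counts$bin == 10], 2)
  expect_equal(ch$counts$count[ch$counts$bin == 7], 2)
  expect_equal(ch$overall_accuracy, 0.75)
  expect_equal(ch$overall_confidence, 0.80)
  # overall confidence is the count-weighted mean of bin confidences
  set.seed(4)
  rt <- random_prediction_table(300)
  bins <- bin_predictions(rt, 10)
  ch2 <- confidence_histogram_data(rt, 10)
  ne <- bins$count > 0
  expect_equal(ch2$overall_confidence,
               sum(bins$count[ne] / 300 * bins$confidence[ne]), tolerance = 1e-9)
})

test_that("per-exit reports cover every head and TS leaves accuracy fixed", {
  set.seed(6)
  cfg <- backbone_config(c(4, 8), c(1, 1), c(16, 16))
  m <- build_model(cfg, seed = 4)
  xte <- array(runif(16 * 16 * 3 * 40), c(16, 16, 3, 40))
  yte <- sample(0:1, 40, replace = TRUE)
  xva <- array(runif(16 * 16 * 3 * 30), c(16, 16, 3, 30))
  yva <- sample(0:1, 30, replace = TRUE)
  out <- forward_with_exits(m, xte)
  vout <- forward_with_exits(m, xva)
  rep0 <- per_exit_report(out, yte)
  rep1 <- per_exit_report(out, yte, apply_ts = TRUE, val_outputs = vout,
                          val_labels = yva)
  expect_equal(nrow(rep0), 3)
  expect_equal(nrow(rep1), 3)
  expect_equal(rep1$accuracy, rep0$accuracy)
  expect_true(all(is.finite(rep1$temperature)))
  expect_error(per_exit_report(out, yte, apply_ts = TRUE), "required")
  m6 <- build_model(vgg_style_config(), seed = 1)
  out6 <- forward_with_exits(m6, array(0.5, c(128, 128, 3, 2)))
  expect_equal(nrow(per_exit_report(out6, c(0, 1))), 6)
})

test_that("prediction tables round-trip through CSV", {
  set.seed(9)
  rt <- random_prediction_table(25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_prediction_table(rt, path)
  back <- read_prediction_table(path)
  expect_equal(back$confidence, rt$confidence, tolerance = 1e-12)
  expect_equal(back$predicted, rt$predicted)
  expect_equal(back$true, rt$true)
})
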
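test_that("the generator produces the requested number of deterministic images", {
  sp <- synth_params(n_patients = 10, images_per_patient = 8, image_size = 24,
                     seed = 5)
  imgs <- generate_synthetic_dataset(sp)
  expect_length(imgs, 80)
  expect_true(all(vapply(imgs, function(i) all(i$pixels >= 0 & i$pixels <= 1),
                         logical(1))))
  expect_length(unique(vapply(imgs, `[[`, character(1), "patient_id")), 10)
  imgs2 <- generate_synthetic_dataset(sp)
  expect_identical(imgs[[37]]$pixels, imgs2[[37]]$pixels)
  expect_identical(vapply(imgs, `[[`, integer(1), "label"),
                   vapply(imgs2, `[[`, integer(1), "label"))
})

test_that("measured N/C area ratios separate the classes for disjoint ranges", {
  sp <- synth_params(n_patients = 8, images_per_patient = 6, image_size = 48,
                     nc_ratio_normal = c(0.15, 0.35),
                     nc_ratio_abnormal = c(0.55, 0.80), seed = 9)
  imgs <- generate_synthetic_dataset(sp)
  labels <- vapply(imgs, `[[`, integer(1), "label")
  measured <- vapply(imgs, function(i) i$meta$nucleus_px / i$meta$cytoplasm_px,
                     numeric(1))
  expect_gt(min(measured[labels == 1]), max(measured[labels == 0]))
  # rasterised areas track the drawn ratios
  drawn <- vapply(imgs, function(i) i$meta$nc_ratio_drawn, numeric(1))
  expect_lt(max(abs(measured - drawn)), 0.12)
  expect_error(synth_params(nc_ratio_normal = c(0.2, 0.6),
                            nc_ratio_abnormal = c(0.5, 0.8)), "strictly above")
})

test_that("four-crop quadrants tile an even image exactly", {
  set.seed(2)
  px <- array(runif(64 * 64 * 3), c(64, 64, 3))
  crops <- four_crop(px)
  expect_length(crops, 4)
  expect_equal(dim(crops[[1]]), c(32, 32, 3))
  rebuilt <- array(0, c(64, 64, 3))
  rebuilt[1:32, 1:32, ] <- crops[[1]]
  rebuilt[1:32, 33:64, ] <- crops[[2]]
  rebuilt[33:64, 1:32, ] <- crops[[3]]
  rebuilt[33:64, 33:64, ] <- crops[[4]]
  expect_identical(rebuilt, px)
})

test_that("four-crop handles odd sizes, labels, resizing and degenerate input", {
  px <- array(runif(17 * 17 * 3), c(17, 17, 3))
  crops <- four_crop(px)
  expect_equal(dim(crops[[1]]), c(8, 8, 3))
  # the bottom-right quadrant starts after the dropped centre row/column
  expect_identical(crops[[4]], px[10:17, 10:17, , drop = FALSE])
  im <- structure(list(pixels = array(0.5, c(16, 16, 3)), label = 1L,
                       patient_id = "P1", meta = NULL), class = "labeled_image")
  lc <- four_crop(im, resize_to = 12)
  expect_equal(dim(lc[[3]]$pixels), c(12, 12, 3))
  expect_equal(lc[[2]]$label, 1L)
  expect_equal(lc[[2]]$patient_id, "P1")
  expect_error(four_crop(array(0, c(1, 5, 3))), "too small")
})

test_that("rotation augmentation quadruples, preserves labels and is cyclic", {
  imgs <- tiny_dataset(n_patients = 3, images_per_patient = 2, seed = 1)
  aug <- rotation_augment(imgs)
  expect_length(aug, 4 * length(imgs))
  for (i in seq_along(imgs)) {
    grp <- aug[(4 * i - 3):(4 * i)]
    expect_true(all(vapply(grp, `[[`, integer(1), "label") == imgs[[i]]$label))
    expect_true(all(vapply(grp, `[[`, character(1), "patient_id") ==
                    imgs[[i]]$patient_id))
  }
  # four successive 90-degree rotations recover the original bit-exactly
  r <- imgs[[1]]
  for (k in 1:4) r <- rotation_augment(list(r))[[2]]
  expect_identical(r$pixels, imgs[[1]]$pixels)
  bad <- structure(list(pixels = array(0, c(4, 6, 3)), label = 0L,
                        patient_id = "P", meta = NULL), class = "labeled_image")
  expect_error(rotation_augment(list(bad)), "square")
})

test_that("patient splits are leakage-free, floor-allocated and deterministic", {
  imgs <- tiny_dataset(n_patients = 10, images_per_patient = 4, seed = 2)
  man <- patient_split(imgs, seed = 7)
  expect_length(man$patients$train, 6)
  expect_length(man$patients$validation, 2)
  expect_length(man$patients$test, 2)
  expect_equal(sort(c(man$train, man$validation, man$test)), seq_along(imgs))
  for (s in 1:10) {
    m <- patient_split(imgs, seed = s)
    expect_length(intersect(m$patients$train, m$patients$validation), 0)
    expect_length(intersect(m$patients$train, m$patients$test), 0)
    expect_length(intersect(m$patients$validation, m$patients$test), 0)
  }
  expect_identical(patient_split(imgs, seed = 7), man)
  two <- imgs[vapply(imgs, `[[`, character(1), "patient_id") %in%
              c("P001", "P002")]
  expect_error(patient_split(two, seed = 1), "at least 3")
  expect_error(patient_split(imgs, fractions = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("split manifests round-trip through JSON", {
  imgs <- tiny_dataset(n_patients = 5, images_per_patient = 3, seed = 4)
  man <- patient_split(imgs, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(man, path)
  back <- read_split_manifest(path)
  expect_equal(back$train, man$train)
  expect_equal(back$patients$test, man$patients$test)
})

test_that("datasets round-trip through PNG files and a CSV manifest", {
  imgs <- tiny_dataset(n_patients = 3, images_per_patient = 1, seed = 6)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(imgs, dir)
  expect_true(file.exists(manifest))
  back <- load_dataset(manifest)
  expect_length(back, 3)
  expect_equal(back[[2]]$label, imgs[[2]]$label)
  expect_equal(back[[2]]$patient_id, imgs[[2]]$patient_id)
  # PNG is 8-bit, so pixels agree to 1/255
  expect_lt(max(abs(back[[1]]$pixels - imgs[[1]]$pixels)), 1 / 254)
})

test_that("grayscale images are replicated to three channels and errors name paths", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(runif(64), 8, 8), file.path(dir, "gray.png"))
  utils::write.csv(data.frame(path = "gray.png", label = 0, patient_id = "P1"),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  back <- load_dataset(file.path(dir, "manifest.csv"))
  expect_equal(dim(back[[1]]$pixels), c(8, 8, 3))
  expect_identical(back[[1]]$pixels[, , 1], back[[1]]$pixels[, , 3])
  utils::write.csv(data.frame(path = "missing.png", label = 0, patient_id = "P1"),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(load_dataset(file.path(dir, "manifest.csv")), "missing.png")
})

test_that("the pipeline multiplies counts only where it should", {
  imgs <- tiny_dataset(n_patients = 6, images_per_patient = 4, seed = 8)
  man <- patient_split(imgs, seed = 5)
  spl <- prepare_splits(imgs, man)
  expect_length(spl$train, 16 * length(man$train))       # 4 crops x 4 rotations
  expect_length(spl$validation, 4 * length(man$validation))
  expect_length(spl$test, 4 * length(man$test))
  raw <- prepare_splits(imgs, man, augment_train = FALSE)
  expect_length(raw$train, 4 * length(man$train))
})

test_that("mean intensity alone separates classes with disjoint darkness ranges", {
  sp <- synth_params(n_patients = 12, images_per_patient = 8, image_size = 24,
                     nucleus_intensity_normal = c(0.50, 0.70),
                     nucleus_intensity_abnormal = c(0.05, 0.25),
                     noise_sd = 0.05, seed = 11)
  imgs <- generate_synthetic_dataset(sp)
  df <- data.frame(y = vapply(imgs, `[[`, integer(1), "label"),
                   m = vapply(imgs, function(i) mean(i$pixels), numeric(1)))
  fit <- stats::glm(y ~ m, family = stats::binomial(), data = df)
  acc <- mean((stats::predict(fit, type = "response") > 0.5) == (df$y == 1))
  expect_gt(acc, 0.8)
})
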
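#' Parameters of the synthetic cytology-image generator
#'
#' The generator emulates the morphology that separates normal from abnormal
#' urothelial cells in Paris-system grading: abnormal cells have a
#' nuclear-to-cytoplasmic (N/C) area ratio above 0.5 and a darker
#' (hyperchromatic) nucleus.  Each image is a light background, an elliptical
#' cytoplasm and a concentric elliptical nucleus whose relative area and
#' intensity are drawn from class-specific ranges; background tint and
#' cytoplasm hue are jittered per synthetic patient and shared across that
#' patient's images.
#'
#' @param n_patients Number of synthetic patients.
#' @param images_per_patient Images drawn per patient.
#' @param abnormal_fraction Probability that an image is abnormal (class 1).
#' @param nc_ratio_normal,nc_ratio_abnormal N/C area-ratio ranges for the two
#'   classes; the abnormal range must lie strictly above the normal one.
#' @param nucleus_intensity_normal,nucleus_intensity_abnormal Nucleus
#'   brightness ranges in `[0, 1]`; the abnormal range is darker
#'   (hyperchromasia analogue).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param image_size Side length of the square RGB images, in pixels.
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   parameters.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_patients = 40, images_per_patient = 20,
                         abnormal_fraction = 0.5,
                         nc_ratio_normal = c(0.28, 0.47),
                         nc_ratio_abnormal = c(0.53, 0.75),
                         nucleus_intensity_normal = c(0.28, 0.52),
                         nucleus_intensity_abnormal = c(0.12, 0.40),
                         noise_sd = 0.15, image_size = 32, seed = 1) {
  stopifnot(n_patients >= 1, images_per_patient >= 1,
            abnormal_fraction > 0, abnormal_fraction < 1,
            noise_sd >= 0, image_size >= 4)
  ranges <- list(nc_ratio_normal, nc_ratio_abnormal,
                 nucleus_intensity_normal, nucleus_intensity_abnormal)
  for (r in ranges) {
    if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1) {
      stop("class ranges must be increasing and within (0, 1)", call. = FALSE)
    }
  }
  if (nc_ratio_abnormal[1] <= nc_ratio_normal[2]) {
    stop("abnormal N/C ratio range must lie strictly above the normal range",
         call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         images_per_patient = as.integer(images_per_patient),
         abnormal_fraction = abnormal_fraction,
         nc_ratio_normal = nc_ratio_normal,
         nc_ratio_abnormal = nc_ratio_abnormal,
         nucleus_intensity_normal = nucleus_intensity_normal,
         nucleus_intensity_abnormal = nucleus_intensity_abnormal,
         noise_sd = noise_sd, image_size = as.integer(image_size),
         seed = as.integer(seed)),
    class = "synth_params"
  )
}

labeled_image <- function(pixels, label, patient_id, meta = NULL) {
  structure(list(pixels = pixels, label = as.integer(label),
                 patient_id = as.character(patient_id), meta = meta),
            class = "labeled_image")
}

ellipse_mask <- function(S, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ys <- matrix(rep(seq_len(S), S), S, S)          # row index
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic cytology dataset
#'
#' Draws `n_patients * images_per_patient` labelled RGB images as described
#' in [synth_params()].  Deterministic: the same parameters (including
#' `seed`) produce bit-identical pixel arrays.  Each image carries a `meta`
#' list with the drawn N/C ratio and the pixel areas of the nucleus and
#' cytoplasm masks actually rasterised, so tests can re-measure the
#' morphology from the generator's own masks.
#'
#' @param params A [synth_params()] object.
#' @return A list of `labeled_image` objects (fields `pixels` (S x S x 3 in
#'   `[0, 1]`), `label` (0 normal / 1 abnormal), `patient_id`, `meta`).
#' @export
generate_synthetic_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  S <- params$image_size
  withr::with_seed(params$seed, {
    images <- vector("list", params$n_patients * params$images_per_patient)
    k <- 0L
    for (p in seq_len(params$n_patients)) {
      pid <- sprintf("P%03d", p)
      bg <- c(0.92, 0.90, 0.93) + stats::runif(3, -0.05, 0.04)
      cyto_col <- c(0.55, 0.75, 0.72) + stats::runif(3, -0.08, 0.08)
      for (j in seq_len(params$images_per_patient)) {
        k <- k + 1L
        label <- stats::rbinom(1L, 1L, params$abnormal_fraction)
        rr <- if (label == 1L) params$nc_ratio_abnormal else params$nc_ratio_normal
        ir <- if (label == 1L) params$nucleus_intensity_abnormal else params$nucleus_intensity_normal
        ratio <- stats::runif(1, rr[1], rr[2])
        nuc_int <- stats::runif(1, ir[1], ir[2])
        cx <- S / 2 + stats::runif(1, -S / 12, S / 12)
        cy <- S / 2 + stats::runif(1, -S / 12, S / 12)
        area <- stats::runif(1, 0.25, 0.42) * S^2
        aspect <- stats::runif(1, 0.7, 1.3)
        theta <- stats::runif(1, 0, pi)
        a <- sqrt(area * aspect / pi)
        b <- area / (pi * a)
        cyto <- ellipse_mask(S, cx, cy, a, b, theta)
        sc <- sqrt(ratio)
        nuc <- ellipse_mask(S, cx, cy, a * sc, b * sc, theta)
        nuc_col <- nuc_int * c(0.80, 0.55, 1.00)
        img <- array(0, c(S, S, 3))
        for (ch in 1:3) {
          plane <- matrix(bg[ch], S, S)
          plane[cyto] <- cyto_col[ch]
          plane[nuc] <- nuc_col[ch]
          img[, , ch] <- plane
        }
        if (params$noise_sd > 0) {
          img <- img + stats::rnorm(length(img), 0, params$noise_sd)
        }
        img <- pmin(pmax(img, 0), 1)
        images[[k]] <- labeled_image(
          img, label, pid,
          meta = list(nc_ratio_drawn = ratio, nucleus_px = sum(nuc),
                      cytoplasm_px = sum(cyto))
        )
      }
    }
    images
  })
}

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' Lays out images as `patient/imageNNN.png` under `dir` and writes
#' `manifest.csv` with columns `path`, `label`, `patient_id` — the same
#' layout [load_dataset()] reads, so synthetic and real data flow through
#' identical code.
#'
#' @param images List of `labeled_image` objects.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    sub <- file.path(dir, im$patient_id)
    dir.create(sub, showWarnings = FALSE)
    rel <- file.path(im$patient_id, sprintf("image%04d.png", i))
    png::writePNG(im$pixels, file.path(dir, rel))
    rows[[i]] <- data.frame(path = rel, label = im$label,
                            patient_id = im$patient_id)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", path, call. = FALSE)
  )
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), c(dim(px), 3L))      # grayscale -> 3 channels
  } else if (dim(px)[3L] == 4L) {
    px <- px[, , 1:3, drop = FALSE]               # drop alpha
  } else if (dim(px)[3L] == 1L) {
    px <- array(rep(px, 3L), c(dim(px)[1:2], 3L))
  }
  px
}

#' Load a labelled image dataset from a CSV manifest
#'
#' @param manifest Path to a CSV with columns `path`, `label`, `patient_id`;
#'   `path` entries are resolved relative to `image_root`.
#' @param image_root Directory containing the image files; defaults to the
#'   manifest's directory.
#' @return A list of `labeled_image` objects with pixel values in `[0, 1]`.
#' @export
load_dataset <- function(manifest, image_root = dirname(manifest)) {
  df <- utils::read.csv(manifest, colClasses = c(path = "character",
                                                 patient_id = "character"))
  if (!all(c("path", "label", "patient_id") %in% names(df))) {
    stop("manifest must have columns path, label, patient_id", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    fp <- file.path(image_root, df$path[i])
    if (!file.exists(fp)) stop("image file not found: ", fp, call. = FALSE)
    labeled_image(read_rgb_image(fp), df$label[i], df$patient_id[i])
  })
}

crop_pixels <- function(px, rows, cols) px[rows, cols, , drop = FALSE]

#' Centre four-crop
#'
#' Cuts an image into the four quadrants meeting at its centre point
#' (top-left, top-right, bottom-left, bottom-right), each of size
#' `floor(H/2) x floor(W/2)`; for even dimensions the quadrants tile the
#' original exactly, for odd dimensions the centre row/column is dropped.
#' `mode = "overlapping"` instead takes four `ceiling`-sized corner crops
#' that share the centre row/column when dimensions are odd.
#'
#' @param image A `labeled_image` or a plain `H x W x 3` array.
#' @param resize_to Optional target side length; crops are bilinearly resized
#'   to `resize_to x resize_to` when given.
#' @param mode `"quadrants"` (default) or `"overlapping"`.
#' @return A list of 4 objects of the same type as the input; crops of a
#'   `labeled_image` inherit its label and patient.
#' @export
four_crop <- function(image, resize_to = NULL, mode = c("quadrants", "overlapping")) {
  mode <- match.arg(mode)
  is_li <- inherits(image, "labeled_image")
  px <- if (is_li) image$pixels else image
  H <- dim(px)[1L]; W <- dim(px)[2L]
  if (H < 2L || W < 2L) stop("image too small to four-crop", call. = FALSE)
  if (mode == "quadrants") {
    h <- H %/% 2L; w <- W %/% 2L
    top <- seq_len(h); bottom <- seq.int(H - h + 1L, H)
    left <- seq_len(w); right <- seq.int(W - w + 1L, W)
  } else {
    h <- ceiling(H / 2); w <- ceiling(W / 2)
    top <- seq_len(h); bottom <- seq.int(H - h + 1L, H)
    left <- seq_len(w); right <- seq.int(W - w + 1L, W)
  }
  crops <- list(crop_pixels(px, top, left), crop_pixels(px, top, right),
                crop_pixels(px, bottom, left), crop_pixels(px, bottom, right))
  if (!is.null(resize_to)) {
    crops <- lapply(crops, function(cr) {
      r <- EBImage::resize(cr, w = resize_to, h = resize_to, filter = "bilinear")
      array(pmin(pmax(r, 0), 1), c(resize_to, resize_to, 3L))
    })
  }
  if (is_li) {
    crops <- lapply(crops, labeled_image, label = image$label,
                    patient_id = image$patient_id)
  }
  crops
}

rot90cw <- function(px) {
  # res[i, j, ] = px[H - j + 1, i, ]
  aperm(px, c(2L, 1L, 3L))[, rev(seq_len(dim(px)[1L])), , drop = FALSE]
}

#' Rotation augmentation
#'
#' Returns, for each square input image, the original plus its rotations by
#' 90, 180 and 270 degrees (labels and patient ids preserved), quadrupling
#' the list.  Intended for the training split only; [prepare_splits()]
#' enforces that convention.
#'
#' @param images List of square `labeled_image` objects.
#' @return A list 4x as long: all originals, then the three rotations of
#'   each, grouped per input image.
#' @export
rotation_augment <- function(images) {
  out <- vector("list", 4L * length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    d <- dim(im$pixels)
    if (d[1L] != d[2L]) stop("rotation augmentation requires square images",
                             call. = FALSE)
    r90 <- rot90cw(im$pixels)
    r180 <- rot90cw(r90)
    r270 <- rot90cw(r180)
    base <- (i - 1L) * 4L
    out[[base + 1L]] <- im
    out[[base + 2L]] <- labeled_image(r90, im$label, im$patient_id)
    out[[base + 3L]] <- labeled_image(r180, im$label, im$patient_id)
    out[[base + 4L]] <- labeled_image(r270, im$label, im$patient_id)
  }
  out
}

#' Patient-level train/validation/test split
#'
#' Shuffles the distinct patients with a seeded RNG and allocates
#' `floor(f1 * P)` of them to training, `floor(f2 * P)` to validation and
#' the remainder to test, then assigns every image to the split of its
#' patient.  Splitting at the patient level guarantees no image leakage
#' between splits for any patient.
#'
#' @param samples List of `labeled_image` objects (or any list whose elements
#'   have a `patient_id` field).
#' @param fractions Length-3 nonnegative fractions summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A `split_manifest`: sample index vectors `train`, `validation`,
#'   `test`, plus the underlying `patients` sets, `fractions` and `seed`.
#' @export
patient_split <- function(samples, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions < 0)) {
    stop("fractions must be 3 nonnegative values summing to 1", call. = FALSE)
  }
  pid <- vapply(samples, function(s) s$patient_id, character(1))
  patients <- unique(pid)
  P <- length(patients)
  if (P < 3L) stop("need at least 3 distinct patients to split", call. = FALSE)
  shuffled <- withr::with_seed(seed, sample(patients))
  n_tr <- floor(fractions[1] * P)
  n_va <- floor(fractions[2] * P)
  p_tr <- shuffled[seq_len(n_tr)]
  p_va <- shuffled[n_tr + seq_len(n_va)]
  p_te <- shuffled[seq.int(n_tr + n_va + 1L, P)]
  structure(
    list(train = which(pid %in% p_tr), validation = which(pid %in% p_va),
         test = which(pid %in% p_te),
         patients = list(train = p_tr, validation = p_va, test = p_te),
         fractions = fractions, seed = as.integer(seed)),
    class = "split_manifest"
  )
}

#' Serialize a split manifest as JSON
#'
#' @param manifest A `split_manifest`.
#' @param path JSON file path.
#' @return `write_split_manifest()` returns `path` invisibly;
#'   `read_split_manifest()` the restored manifest.
#' @export
write_split_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$train <- as.integer(obj$train)
  obj$validation <- as.integer(obj$validation)
  obj$test <- as.integer(obj$test)
  structure(obj, class = "split_manifest")
}

#' Run the full preprocessing pipeline over a split dataset
#'
#' Applies the centre four-crop to every image of every split (each crop
#' becomes its own sample, inheriting label and patient) and rotation
#' augmentation to the training split only, mirroring the standard pipeline
#' for small cytology datasets.
#'
#' @param images Full list of `labeled_image` objects.
#' @param manifest A [patient_split()] manifest over `images`.
#' @param resize_to Optional side length for resizing the crops.
#' @param augment_train Apply the 4x rotation augmentation to training.
#' @return A list with elements `train`, `validation`, `test`, each a list of
#'   `labeled_image` crops.
#' @export
prepare_splits <- function(images, manifest, resize_to = NULL,
                           augment_train = TRUE) {
  crop_all <- function(idx) {
    unlist(lapply(images[idx], four_crop, resize_to = resize_to),
           recursive = FALSE)
  }
  train <- crop_all(manifest$train)
  if (augment_train) train <- rotation_augment(train)
  list(train = train, validation = crop_all(manifest$validation),
       test = crop_all(manifest$test))
}

#' Stack labelled images into a model-ready batch
#'
#' @param images List of equally sized `labeled_image` objects.
#' @return A list with `x` (`H x W x 3 x N` array) and `labels` (zero-based
#'   integer vector).
#' @export
images_to_batch <- function(images) {
  if (length(images) == 0L) stop("empty image list", call. = FALSE)
  d <- dim(images[[1L]]$pixels)
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]$pixels
  list(x = x, labels = vapply(images, function(im) im$label, integer(1)))
}
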
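#' Read an image and its per-class annotation masks from disk
#'
#' Reads a single-channel image (PNG or single-page TIFF) together with one
#' binary mask file per class. Mask files use the on-disk convention
#' 0 = background, 255 = foreground; any strictly positive pixel is
#' binarized to 1 in memory.
#'
#' @param image_path Path to the grayscale image.
#' @param mask_paths Named character vector or list mapping each class in
#'   [segmentation_classes()] to its mask file.
#' @param id Instance identifier; defaults to the image file name without
#'   extension.
#' @return An [annotated_instance()] with 8-bit integer image pixels.
#' @export
read_instance <- function(image_path, mask_paths, id = NULL) {
  if (!file.exists(image_path)) stop_contract("image file not found: %s", image_path)
  id <- id %||% sub("\\.[^.]+$", "", basename(image_path))
  image <- read_gray(image_path)
  classes <- segmentation_classes()
  mask_paths <- as.list(mask_paths)
  if (!setequal(names(mask_paths), classes)) {
    stop_contract("mask_paths must name exactly the classes: %s",
                  paste(classes, collapse = ", "))
  }
  masks <- lapply(classes, function(cl) {
    p <- mask_paths[[cl]]
    if (!file.exists(p)) stop_contract("mask file not found: %s", p)
    m <- read_gray(p)
    if (!identical(dim(m), dim(image))) {
      stop_contract("mask file %s is %dx%d but image %s is %dx%d",
                    p, nrow(m), ncol(m), image_path, nrow(image), ncol(image))
    }
    matrix(as.integer(m > 0), nrow(m), ncol(m))
  })
  names(masks) <- classes
  annotated_instance(image, masks, id)
}

#' Read a multi-page TIFF stack as a list of grayscale frames
#'
#' Each page becomes one integer `[row, col]` matrix in 0..255, in page
#' order. Single-page files yield a list of length 1.
#'
#' @param path Path to a (multi-page) TIFF or other raster file.
#' @return List of integer matrices.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_contract("image file not found: %s", path)
  img <- EBImage::imageData(EBImage::readImage(path, all = TRUE))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  lapply(seq_len(dim(img)[3L]), function(k) {
    m <- t(img[, , k])
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
}

# Read a grayscale raster as an integer [row, col] matrix in 0..255.
# EBImage stores pixels [x = column, y = row] scaled to [0, 1]; transpose
# and rescale to the package convention. Multi-channel input is averaged.
read_gray <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  m <- t(img)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write an instance's image and masks to disk
#'
#' Counterpart of [read_instance()]: the image is written as an 8-bit
#' grayscale raster and each mask as 0/255. File names follow the
#' `<id>.png`, `<id>_<class>.png` suffix convention.
#'
#' @param instance An [annotated_instance()].
#' @param dir Output directory (created if missing).
#' @param format `"png"` (default) or `"tiff"`.
#' @return Invisibly, a named list of the written paths.
#' @export
write_instance <- function(instance, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- instance$image
  if (max(px) <= 1) px <- px * 255  # preprocessed image written back on the 8-bit scale
  paths <- list(image = file.path(dir, sprintf("%s.%s", instance$id, format)))
  EBImage::writeImage(EBImage::Image(t(px / 255)), paths$image)
  for (cl in names(instance$masks)) {
    p <- file.path(dir, sprintf("%s_%s.%s", instance$id, cl, format))
    EBImage::writeImage(EBImage::Image(t(instance$masks[[cl]])), p)
    paths[[cl]] <- p
  }
  invisible(paths)
}

#' Histogram equalization on the 8-bit lattice
#'
#' Classic global equalization: each intensity is mapped through the scaled
#' empirical CDF over 256 bins,
#' `T(v) = round(255 * (cdf(v) - cdf_min) / (n - cdf_min))`,
#' where `cdf_min` is the CDF value of the darkest occupied bin. A constant
#' image has no contrast to redistribute and is returned unchanged.
#'
#' @param pixels Integer matrix with values in 0--255.
#' @return Integer matrix of the same shape, values in 0--255.
#' @export
hist_equalize <- function(pixels) {
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_contract("hist_equalize expects 8-bit input in 0..255")
  }
  counts <- tabulate(as.integer(pixels) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- cdf[cdf > 0][1L]
  n <- length(pixels)
  if (n == cdf_min) return(pixels)  # constant image
  lut <- as.integer(round(255 * (cdf - cdf_min) / (n - cdf_min)))
  matrix(lut[as.integer(pixels) + 1L], nrow(pixels), ncol(pixels))
}

#' Preprocess a raw 8-bit image for the network
#'
#' Histogram-equalizes the image to enhance contrast, then scales to
#' \[0, 1\] by dividing by 255.
#'
#' @param pixels Integer matrix with values in 0--255.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
preprocess <- function(pixels) {
  if (!is.matrix(pixels)) stop_contract("preprocess expects a matrix")
  if (min(pixels) < 0 || max(pixels) > 255 || any(pixels != round(pixels))) {
    stop_contract("preprocess expects 8-bit integer input in 0..255")
  }
  hist_equalize(pixels) / 255
}

#' Randomly split instances into train/validation/test partitions
#'
#' Partition sizes are the largest-remainder rounding of `ratios * n`, and
#' the assignment is a seeded permutation, so the same seed always yields
#' the same split. The gold-standard partition is never drawn from these
#' instances; supply it separately to [dataset_split()].
#'
#' @param instances List of [annotated_instance()] objects.
#' @param ratios Numeric vector of length 3 (train, validation, test)
#'   summing to 1. Default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed for the permutation.
#' @param gold Optional list of pristine gold instances.
#' @return A [dataset_split()].
#' @export
split_dataset <- function(instances, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          gold = list()) {
  n <- length(instances)
  if (n < 3L) stop_contract("need at least as many instances as partitions")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8) {
    stop_contract("ratios must be 3 values summing to 1")
  }
  raw <- ratios * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_by_frac <- order(raw - sizes, decreasing = TRUE)
    sizes[order_by_frac[seq_len(rem)]] <- sizes[order_by_frac[seq_len(rem)]] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  cut1 <- sizes[1L]
  cut2 <- sizes[1L] + sizes[2L]
  dataset_split(train = instances[perm[seq_len(cut1)]],
                validation = instances[perm[(cut1 + 1L):cut2]],
                test = instances[perm[(cut2 + 1L):n]],
                gold = gold)
}

#' Sample the parameters of one random geometric transform
#'
#' @param seed Integer seed.
#' @param max_rotation Rotation range in degrees (plus/minus).
#' @param max_shift Maximum shift as a fraction of the image side.
#' @param zoom_range Length-2 numeric, multiplicative zoom bounds.
#' @param flips If `TRUE`, horizontal and vertical flips are sampled
#'   independently with probability 0.5.
#' @return A named list understood by [apply_transform()].
#' @export
sample_transform <- function(seed, max_rotation = 25, max_shift = 0.1,
                             zoom_range = c(0.9, 1.1), flips = TRUE) {
  with_seed(seed, list(
    flip_h = flips && runif(1) < 0.5,
    flip_v = flips && runif(1) < 0.5,
    angle  = runif(1, -max_rotation, max_rotation),
    zoom   = runif(1, zoom_range[1L], zoom_range[2L]),
    shift_r = round(runif(1, -max_shift, max_shift) * 1000) / 1000,
    shift_c = round(runif(1, -max_shift, max_shift) * 1000) / 1000
  ))
}

# Inverse-map affine sampling. The rotation+zoom+shift are composed into a
# single affine transform about the image centre and applied in one
# interpolation step; flips are exact index reversals applied first.
# method "bilinear" is used for images (reflective coordinate folding at the
# borders), "nearest" for masks (out-of-frame samples become background 0 so
# foreground is never duplicated by reflection). Multiples of 90 degrees use
# exact cos/sin so they are pure pixel permutations.
affine_sample <- function(px, angle, zoom, shift_r, shift_c,
                          method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(px); w <- ncol(px)
  if (angle %% 90 == 0) {
    k <- (angle / 90) %% 4
    co <- c(1, 0, -1, 0)[k + 1L]
    si <- c(0, 1, 0, -1)[k + 1L]
  } else {
    th <- angle * pi / 180
    co <- cos(th); si <- sin(th)
  }
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  dst <- expand.grid(r = 0:(h - 1), c = 0:(w - 1))
  # inverse map: dst -> src (rotate by -angle, scale by 1/zoom, unshift)
  dr <- dst$r - cr - shift_r * h
  dc <- dst$c - cc - shift_c * w
  src_r <- ( co * dr + si * dc) / zoom + cr
  src_c <- (-si * dr + co * dc) / zoom + cc
  if (method == "nearest") {
    ir <- round(src_r); ic <- round(src_c)
    inside <- ir >= 0 & ir < h & ic >= 0 & ic < w
    out <- numeric(h * w)
    out[inside] <- px[cbind(ir[inside] + 1, ic[inside] + 1)]
    out <- matrix(out, h, w)
    if (is.integer(px)) out <- matrix(as.integer(out), h, w)
    out
  } else {
    reflect <- function(x, n) {
      # fold coordinates into [0, n-1] (mirror at the borders)
      if (n == 1L) return(rep(0, length(x)))
      p <- 2 * (n - 1)
      x <- abs(x) %% p
      ifelse(x > (n - 1), p - x, x)
    }
    src_r <- reflect(src_r, h); src_c <- reflect(src_c, w)
    r0 <- pmin(floor(src_r), h - 1); c0 <- pmin(floor(src_c), w - 1)
    r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
    fr <- src_r - r0; fc <- src_c - c0
    v <- px[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
      px[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
      px[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
      px[cbind(r1 + 1, c1 + 1)] * fr * fc
    matrix(v, h, w)
  }
}

flip_matrix <- function(px, horizontal = FALSE, vertical = FALSE) {
  if (horizontal) px <- px[, ncol(px):1, drop = FALSE]
  if (vertical) px <- px[nrow(px):1, , drop = FALSE]
  px
}

#' Apply one geometric transform to an instance
#'
#' The identical transform is applied to the image and to every mask:
#' flips first (exact index reversals), then a single affine resampling
#' combining rotation, zoom and shift. Images are sampled bilinearly with
#' reflective borders; masks use nearest-neighbour sampling with background
#' fill, so they remain strictly binary.
#'
#' @param instance An [annotated_instance()].
#' @param tf Transform parameters from [sample_transform()], or a list with
#'   fields `flip_h`, `flip_v`, `angle` (degrees), `zoom`, `shift_r`,
#'   `shift_c` (fractions of the side).
#' @param id Identifier for the transformed instance.
#' @return A new [annotated_instance()] with provenance `"augmented"`.
#' @export
apply_transform <- function(instance, tf, id = paste0(instance$id, "_aug")) {
  img <- flip_matrix(instance$image, tf$flip_h, tf$flip_v)
  img <- affine_sample(img, tf$angle, tf$zoom, tf$shift_r, tf$shift_c, "bilinear")
  if (is.integer(instance$image)) {
    img <- matrix(as.integer(pmin(pmax(round(img), 0L), 255L)), nrow(img), ncol(img))
  }
  masks <- lapply(instance$masks, function(m) {
    m <- flip_matrix(m, tf$flip_h, tf$flip_v)
    m <- affine_sample(m, tf$angle, tf$zoom, tf$shift_r, tf$shift_c, "nearest")
    matrix(as.integer(m), nrow(m), ncol(m))
  })
  annotated_instance(img, masks, id, provenance = "augmented",
                     gt_masks = instance$gt_masks)
}

#' Augment a training set by random geometric transforms
#'
#' Expands the training set to `factor` times its size: the originals are
#' kept and each original contributes `factor - 1` transformed copies, each
#' applying one random flip/rotation/zoom/shift combination identically to
#' the image and all masks. No further augmentation is applied after this
#' step; later boosting iterations reuse the expanded set as-is, and sample
#' weights attach to the expanded instances.
#'
#' @param instances Training instances.
#' @param factor Integer >= 1; output size is `factor * length(instances)`.
#' @param seed Integer seed; the same seed reproduces every transform.
#' @inheritParams sample_transform
#' @return List of [annotated_instance()] objects.
#' @export
augment_dataset <- function(instances, factor = 3L, seed = 1L,
                            max_rotation = 25, max_shift = 0.1,
                            zoom_range = c(0.9, 1.1), flips = TRUE) {
  if (factor < 1L) stop_contract("factor must be >= 1")
  if (factor == 1L) return(instances)
  out <- instances
  k <- 0L
  for (i in seq_along(instances)) {
    for (j in seq_len(factor - 1L)) {
      k <- k + 1L
      tf <- sample_transform(seed + k, max_rotation, max_shift, zoom_range, flips)
      out[[length(out) + 1L]] <- apply_transform(
        instances[[i]], tf, id = sprintf("%s_aug%d", instances[[i]]$id, j))
    }
  }
  out
}

#' Write a dataset manifest CSV
#'
#' One row per instance: id, image path, one mask path per class, and the
#' partition name.
#'
#' @param split A [dataset_split()].
#' @param dir Dataset directory containing the image files.
#' @param file Output CSV path, default `manifest.csv` inside `dir`.
#' @return Invisibly, the manifest data frame.
#' @export
write_manifest <- function(split, dir, file = file.path(dir, "manifest.csv")) {
  rows <- list()
  for (part in names(split)) {
    for (inst in split[[part]]) {
      row <- data.frame(id = inst$id,
                        image = file.path(part, paste0(inst$id, ".png")),
                        partition = part, stringsAsFactors = FALSE)
      for (cl in segmentation_classes()) {
        row[[paste0("mask_", cl)]] <- file.path(part, sprintf("%s_%s.png", inst$id, cl))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset back from a manifest CSV
#'
#' @param file Manifest CSV written by [write_manifest()].
#' @return A [dataset_split()].
#' @export
read_manifest <- function(file) {
  manifest <- read.csv(file, stringsAsFactors = FALSE)
  base <- dirname(file)
  parts <- list(train = list(), validation = list(), test = list(), gold = list())
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    mp <- setNames(file.path(base, unlist(row[paste0("mask_", segmentation_classes())])),
                   segmentation_classes())
    inst <- read_instance(file.path(base, row$image), mp, id = row$id)
    parts[[row$partition]][[length(parts[[row$partition]]) + 1L]] <- inst
  }
  dataset_split(parts$train, parts$validation, parts$test, parts$gold)
}
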
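test_that("read_instance validates shapes and binarizes 0/255 masks", {
  dir <- withr::local_tempdir()
  img <- matrix(as.integer(round(runif(64 * 64, 0, 255))), 64, 64)
  soma <- blob(64, 64, 10, 10, 5, 5)
  vessel <- blob(64, 64, 40, 40, 3, 8)
  inst <- annotated_instance(img, list(soma = soma, vessel = vessel), "a1")
  paths <- write_instance(inst, dir)
  back <- read_instance(paths$image, list(soma = paths$soma, vessel = paths$vessel))
  expect_identical(dim(back$image), c(64L, 64L))
  expect_identical(back$masks$soma, soma)
  expect_identical(back$masks$vessel, vessel)
  expect_true(all(unlist(back$masks) %in% c(0L, 1L)))
  expect_equal(back$image, img, tolerance = 0)  # 8-bit roundtrip is exact

  # mismatched mask shape is a structural error naming the file
  small <- annotated_instance(matrix(0L, 32, 32),
                              list(soma = matrix(0L, 32, 32),
                                   vessel = matrix(0L, 32, 32)), "small")
  p2 <- write_instance(small, dir)
  expect_error(
    read_instance(paths$image, list(soma = p2$soma, vessel = paths$vessel)),
    "32x32")
})

test_that("histogram equalization follows the CDF-mapping oracle", {
  # uniformly distributed intensities: equalization is the identity
  px <- matrix(rep(0:255, each = 4L), 32, 32)
  expect_identical(hist_equalize(px), px)
  expect_equal(max(abs(preprocess(px) - px / 255)), 0, tolerance = 1 / 255)

  # general image: compare against a direct CDF-mapping oracle
  set.seed(42)
  px <- matrix(as.integer(rbinom(900, 255, 0.3)), 30, 30)
  eq <- hist_equalize(px)
  n <- length(px)
  counts <- tabulate(px + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cmin <- cdf[cdf > 0][1L]
  oracle <- matrix(as.integer(round(255 * (cdf[px + 1L] - cmin) / (n - cmin))),
                   30, 30)
  expect_identical(eq, oracle)
  # endpoint: the brightest occupied bin maps to 255
  expect_identical(max(eq), 255L)
})

test_that("constant images pass through equalization unchanged", {
  px <- matrix(77L, 8, 8)
  expect_identical(hist_equalize(px), px)
  expect_equal(preprocess(px), px / 255)
  expect_error(preprocess(matrix(300L, 2, 2)), "8-bit")
})

test_that("split_dataset produces rounded, seeded, disjoint partitions", {
  mk <- function(n) lapply(seq_len(n), function(i) {
    make_instance(matrix(0L, 4, 4), matrix(0L, 4, 4), id = paste0("i", i))
  })
  insts <- mk(1000)
  sp <- split_dataset(insts, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 800L, validation = 100L, test = 100L))
  sp2 <- split_dataset(insts, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(sapply(sp$train, `[[`, "id"), sapply(sp2$train, `[[`, "id"))
  # disjoint and exhaustive
  ids <- unname(unlist(lapply(sp[c("train", "validation", "test")],
                              function(p) sapply(p, `[[`, "id"))))
  expect_identical(sort(ids), sort(sapply(insts, `[[`, "id")))

  sp10 <- split_dataset(mk(10), c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(lengths(sp10[c("train", "validation", "test")]),
                   c(train = 8L, validation = 1L, test = 1L))
  expect_error(split_dataset(list()), "at least")
})

test_that("augmentation multiplies the set and transforms image and masks together", {
  insts <- lapply(1:4, function(i) generate_phantom(seed = i, id = paste0("p", i)))
  out <- augment_dataset(insts, factor = 3L, seed = 5)
  expect_length(out, 12L)
  expect_identical(out[1:4], insts)
  expect_true(all(sapply(out[5:12], `[[`, "provenance") == "augmented"))
  # masks stay binary after resampling
  for (x in out) expect_true(all(unlist(x$masks) %in% c(0L, 1L)))
  # identity factor
  expect_identical(augment_dataset(insts, factor = 1L), insts)
  # same seed reproduces the transforms exactly
  out2 <- augment_dataset(insts, factor = 3L, seed = 5)
  expect_identical(out, out2)
})

test_that("horizontal flip maps mask pixel (r, c) to (r, W - 1 - c)", {
  m <- matrix(0L, 4, 4); m[2, 1] <- 1L  # one-hot at 0-based (1, 0)
  inst <- make_instance(m, matrix(0L, 4, 4))
  tf <- list(flip_h = TRUE, flip_v = FALSE, angle = 0, zoom = 1,
             shift_r = 0, shift_c = 0)
  got <- apply_transform(inst, tf)
  want <- matrix(0L, 4, 4); want[2, 4] <- 1L  # 0-based column 3 = W-1-0
  expect_identical(got$masks$soma, want)
})

test_that("flips and 90-degree rotations preserve mask pixel counts exactly", {
  inst <- generate_phantom(seed = 11, id = "p")
  for (tf in list(list(flip_h = TRUE, flip_v = FALSE, angle = 0, zoom = 1, shift_r = 0, shift_c = 0),
                  list(flip_h = FALSE, flip_v = TRUE, angle = 0, zoom = 1, shift_r = 0, shift_c = 0),
                  list(flip_h = FALSE, flip_v = FALSE, angle = 90, zoom = 1, shift_r = 0, shift_c = 0),
                  list(flip_h = TRUE, flip_v = FALSE, angle = 270, zoom = 1, shift_r = 0, shift_c = 0))) {
    got <- apply_transform(inst, tf)
    expect_identical(sum(got$masks$soma), sum(inst$masks$soma))
    expect_identical(sum(got$masks$vessel), sum(inst$masks$vessel))
  }
})

test_that("manifest roundtrips a dataset split", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, 1, 1, 1, seed = 3, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "corruption_log.csv")))
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(lengths(back), lengths(ds$split))
  expect_identical(back$train[[1]]$masks, ds$split$train[[1]]$masks)
  expect_identical(back$gold[[1]]$image, ds$split$gold[[1]]$image)
})

test_that("multi-page TIFF stacks read as per-frame matrices", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "stack.tif")
  frames <- array(sample(0:255, 32 * 32 * 3, replace = TRUE) / 255,
                  c(32, 32, 3))
  EBImage::writeImage(EBImage::Image(frames), f, bits.per.sample = 8L)
  got <- read_stack(f)
  expect_length(got, 3L)
  for (k in 1:3) {
    expect_identical(dim(got[[k]]), c(32L, 32L))
    expect_identical(got[[k]], matrix(as.integer(round(t(frames[, , k]) * 255)),
                                      32, 32))
  }
})
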
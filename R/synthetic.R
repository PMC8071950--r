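#' Configuration of the synthetic MOST-like phantom generator
#'
#' Phantoms emulate the appearance of Nissl-stained micro-optical sectioning
#' tomography frames: neuronal somata as dark-gray filled ellipses, and
#' vessels as bright-white structures on a noisy mid-gray background. The
#' vessel class mixes two morphologies seen in 2D slices of a 3D
#' vasculature: elongated random-walk tubes (vessels running within the
#' section plane) and small circular cross-sections (vessels piercing it).
#' Intensity bands are on the 8-bit scale and must be ordered
#' soma < background < vessel.
#'
#' @param size Image side in pixels (square), default 64.
#' @param n_somata Length-2 integer range of soma count, default `c(2, 5)`.
#' @param soma_radius Length-2 range of soma semi-axis in pixels, default
#'   `c(3, 7)`.
#' @param n_vessels Length-2 integer range of in-plane vessel tube count,
#'   default `c(1, 3)`.
#' @param vessel_thickness Length-2 range of tube radius in pixels, default
#'   `c(1, 2)`.
#' @param n_xsections Length-2 integer range of small circular vessel
#'   cross-sections, default `c(2, 6)`.
#' @param xsection_radius Length-2 range of cross-section radius in pixels,
#'   default `c(1.5, 3)`.
#' @param tortuosity Standard deviation (radians) of the per-step direction
#'   perturbation of the vessel random walk, default 0.25.
#' @param background_mean,background_sd Background band, default 128 / 4.
#' @param soma_mean,vessel_mean Mean intensity inside somata (default 70)
#'   and vessels (default 225).
#' @param noise_sd Additive Gaussian pixel noise, default 8.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(size = 64L, n_somata = c(2L, 5L),
                           soma_radius = c(3, 7), n_vessels = c(1L, 3L),
                           vessel_thickness = c(1, 2),
                           n_xsections = c(2L, 6L), xsection_radius = c(1.5, 3),
                           tortuosity = 0.25,
                           background_mean = 128, background_sd = 4,
                           soma_mean = 70, vessel_mean = 225, noise_sd = 8) {
  if (!(soma_mean < background_mean && background_mean < vessel_mean)) {
    stop_contract("intensity bands must be ordered soma < background < vessel")
  }
  if (any(c(soma_mean, background_mean, vessel_mean) < 0) ||
      any(c(soma_mean, background_mean, vessel_mean) > 255)) {
    stop_contract("intensity bands must lie within 0..255")
  }
  structure(list(size = as.integer(size), n_somata = n_somata,
                 soma_radius = soma_radius, n_vessels = n_vessels,
                 vessel_thickness = vessel_thickness,
                 n_xsections = n_xsections, xsection_radius = xsection_radius,
                 tortuosity = tortuosity,
                 background_mean = background_mean, background_sd = background_sd,
                 soma_mean = soma_mean, vessel_mean = vessel_mean,
                 noise_sd = noise_sd),
            class = "phantom_config")
}

#' Configuration of the annotation-corruption model
#'
#' Emulates the error taxonomy of human annotations: whole labels that are
#' *missing*, adjacent labels merged into *overlapped* labels by sloppy
#' boundaries, and (rarely) *fake* labels for objects that do not exist.
#' All three act component-wise on the ground-truth masks. Only
#' *diminutive* components (up to `miss_max_size` pixels) are eligible to
#' be missed — annotators overlook small, low-salience objects, not the
#' largest structure in a frame. The defaults keep annotations mostly
#' accurate with missing + overlapped labels accounting for ~95 % of the
#' injected errors, missing being the dominant type.
#'
#' @param p_missing Probability that an eligible (small) ground-truth
#'   component is deleted from the annotation, default 0.10.
#' @param p_overlap Probability that a component is dilated until it merges
#'   with a neighbouring component, default 0.03 (skipped when the class
#'   has a single component — there is nothing to merge with).
#' @param p_fake Probability (per ground-truth component) of inserting a
#'   spurious component strictly disjoint from the ground truth, default
#'   0.008.
#' @param miss_max_size Components larger than this many pixels are never
#'   deleted, default 80.
#' @param max_dilate Cap on the overlap-dilation radius in pixels, default 4.
#' @return A list of class `corruption_config`.
#' @export
corruption_config <- function(p_missing = 0.10, p_overlap = 0.03,
                              p_fake = 0.008, miss_max_size = 80L,
                              max_dilate = 4L) {
  for (p in c(p_missing, p_overlap, p_fake)) {
    if (p < 0 || p > 1) stop_contract("corruption probabilities must lie in [0, 1]")
  }
  structure(list(p_missing = p_missing, p_overlap = p_overlap,
                 p_fake = p_fake, miss_max_size = as.integer(miss_max_size),
                 max_dilate = as.integer(max_dilate)),
            class = "corruption_config")
}

# Draw one integer uniformly from [lo, hi]; immune to R's sample(n, 1)
# scalar expansion when lo == hi.
sample_count <- function(range) {
  lo <- as.integer(range[1L]); hi <- as.integer(range[2L])
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Render a filled (possibly rotated) ellipse into a 0/1 matrix.
render_ellipse <- function(size, cr, cc, r1, r2, theta) {
  rc <- expand.grid(r = seq_len(size), c = seq_len(size))
  dr <- rc$r - cr; dc <- rc$c - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  matrix(as.integer((u / r1)^2 + (v / r2)^2 <= 1), size, size)
}

# Render one vessel as a random-walk tube of the given radius. The walk
# starts on a border, heads inward, and its direction diffuses with the
# configured tortuosity; thickness is stamped as a disk along the path.
render_vessel <- function(size, radius, tortuosity) {
  side <- sample.int(4L, 1L)
  pos <- switch(side,
                c(1, runif(1, 1, size)),            # top
                c(size, runif(1, 1, size)),         # bottom
                c(runif(1, 1, size), 1),            # left
                c(runif(1, 1, size), size))         # right
  dir <- switch(side, pi / 2, -pi / 2, 0, pi)       # inward in (row, col) angle terms
  dir <- dir + runif(1, -0.5, 0.5)
  mask <- matrix(0L, size, size)
  rs <- seq_len(size)
  for (step in seq_len(3L * size)) {
    rr <- pos[1L]; cc <- pos[2L]
    sel_r <- rs[abs(rs - rr) <= radius + 0.5]
    sel_c <- rs[abs(rs - cc) <= radius + 0.5]
    if (length(sel_r) && length(sel_c)) {
      d2 <- outer((sel_r - rr)^2, (sel_c - cc)^2, `+`)
      mask[sel_r, sel_c][d2 <= (radius + 0.5)^2] <- 1L
    }
    dir <- dir + rnorm(1, 0, tortuosity)
    pos <- pos + c(cos(dir), sin(dir))
    if (pos[1L] < 1 - radius || pos[1L] > size + radius ||
        pos[2L] < 1 - radius || pos[2L] > size + radius) break
  }
  mask
}

#' Generate one synthetic MOST-like phantom
#'
#' Renders somata (dark filled ellipses) and vessels (bright random-walk
#' tubes) on a noisy mid-gray background and returns the 8-bit image with
#' the exact rendered supports as ground-truth masks. Vessels are drawn on
#' top of somata; pixels a vessel overdraws are removed from the soma mask
#' so each mask is the support of the tissue actually visible there. The
#' same seed reproduces the phantom bit-identically.
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer seed.
#' @param id Instance identifier.
#' @return An [annotated_instance()] whose masks are the pristine ground
#'   truth (also stored in `gt_masks`).
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L, id = "phantom") {
  with_seed(seed, {
    size <- cfg$size
    soma <- matrix(0L, size, size)
    n_s <- sample_count(cfg$n_somata)
    if (n_s > 0) {
      for (k in seq_len(n_s)) {
        r1 <- runif(1, cfg$soma_radius[1L], cfg$soma_radius[2L])
        r2 <- runif(1, cfg$soma_radius[1L], cfg$soma_radius[2L])
        e <- render_ellipse(size, runif(1, 1 + r1, size - r1),
                            runif(1, 1 + r2, size - r2), r1, r2,
                            runif(1, 0, pi))
        soma <- matrix(as.integer(soma | e), size, size)
      }
    }
    vessel <- matrix(0L, size, size)
    n_v <- sample_count(cfg$n_vessels)
    if (n_v > 0) {
      for (k in seq_len(n_v)) {
        radius <- runif(1, cfg$vessel_thickness[1L], cfg$vessel_thickness[2L])
        vessel <- matrix(as.integer(vessel | render_vessel(size, radius, cfg$tortuosity)),
                         size, size)
      }
    }
    # small circular cross-sections of vessels piercing the section plane
    n_x <- sample_count(cfg$n_xsections)
    if (n_x > 0) {
      for (k in seq_len(n_x)) {
        r <- runif(1, cfg$xsection_radius[1L], cfg$xsection_radius[2L])
        e <- render_ellipse(size, runif(1, 1 + r, size - r),
                            runif(1, 1 + r, size - r), r, r, 0)
        vessel <- matrix(as.integer(vessel | e), size, size)
      }
    }
    soma[vessel == 1L] <- 0L  # vessels are drawn on top
    img <- matrix(rnorm(size * size, cfg$background_mean, cfg$background_sd),
                  size, size)
    img[soma == 1L] <- cfg$soma_mean
    img[vessel == 1L] <- cfg$vessel_mean
    img <- img + rnorm(size * size, 0, cfg$noise_sd)
    img <- matrix(as.integer(pmin(pmax(round(img), 0L), 255L)), size, size)
    masks <- list(soma = soma, vessel = vessel)
    annotated_instance(img, masks, id, gt_masks = masks)
  })
}

# Dilate a component (0/1 matrix) by a disk of the given integer radius.
dilate_disk <- function(mask, radius) {
  if (radius < 1L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  offsets <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offsets <- offsets[offsets$dr^2 + offsets$dc^2 <= radius^2, ]
  idx <- which(mask == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(offsets))) {
    r <- idx[, 1L] + offsets$dr[k]; c <- idx[, 2L] + offsets$dc[k]
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    out[cbind(r[ok], c[ok])] <- 1L
  }
  out
}

#' Corrupt ground-truth annotation masks
#'
#' Applies the component-wise error model of [corruption_config()] to a
#' named list of per-class masks. Missing errors delete whole components
#' (never partial erosion); overlap errors dilate a component just enough
#' to touch its nearest neighbour (capped), merging adjacent labels; fake
#' errors insert small elliptical components strictly disjoint from the
#' ground truth of both classes. Every injection is logged with its pixel
#' set, so missing and fake errors can be replayed exactly.
#'
#' @param masks Named list of ground-truth 0/1 masks (one per class).
#' @param ccfg A [corruption_config()].
#' @param seed Integer seed.
#' @return A list with `masks` (corrupted), and `log` — a data frame with
#'   columns `type` (`missing`/`overlap`/`fake`), `class`, `component`,
#'   `n_pixels`, `pixels` (semicolon-joined linear indices of the pixels
#'   removed or added).
#' @export
corrupt_annotations <- function(masks, ccfg = corruption_config(), seed = 1L) {
  with_seed(seed, {
    log <- list()
    out <- masks
    all_gt <- Reduce(`|`, masks) * 1L
    for (cl in names(masks)) {
      gt <- masks[[cl]]
      comp <- connected_components(gt, 8L)
      cur <- gt
      if (comp$n_components > 0) {
        for (ci in seq_len(comp$n_components)) {
          pix <- which(comp$label_map == ci)
          if (length(pix) <= ccfg$miss_max_size && runif(1) < ccfg$p_missing) {
            cur[pix] <- 0L
            log[[length(log) + 1L]] <- data.frame(
              type = "missing", class = cl, component = ci,
              n_pixels = length(pix),
              pixels = paste(pix, collapse = ";"), stringsAsFactors = FALSE)
          } else if (comp$n_components > 1L && runif(1) < ccfg$p_overlap) {
            others <- comp$label_map > 0L & comp$label_map != ci
            this <- matrix(0L, nrow(gt), ncol(gt)); this[pix] <- 1L
            grown <- this
            for (rad in seq_len(ccfg$max_dilate)) {
              grown <- dilate_disk(this, rad)
              if (any(grown[others])) break
            }
            added <- which(grown == 1L & cur == 0L)
            if (length(added)) {
              cur[added] <- 1L
              log[[length(log) + 1L]] <- data.frame(
                type = "overlap", class = cl, component = ci,
                n_pixels = length(added),
                pixels = paste(added, collapse = ";"), stringsAsFactors = FALSE)
            }
          }
          if (runif(1) < ccfg$p_fake) {
            fk <- place_fake_component(all_gt | cur, nrow(gt))
            if (!is.null(fk)) {
              cur[fk] <- 1L
              log[[length(log) + 1L]] <- data.frame(
                type = "fake", class = cl, component = ci,
                n_pixels = length(fk),
                pixels = paste(fk, collapse = ";"), stringsAsFactors = FALSE)
            }
          }
        }
      }
      out[[cl]] <- cur
    }
    log <- if (length(log)) do.call(rbind, log) else
      data.frame(type = character(0), class = character(0),
                 component = integer(0), n_pixels = integer(0),
                 pixels = character(0), stringsAsFactors = FALSE)
    list(masks = out, log = log)
  })
}

# Rejection-sample a small elliptical blob strictly disjoint (with a
# 1-pixel margin) from `occupied`; returns linear pixel indices or NULL.
place_fake_component <- function(occupied, size) {
  occ_dil <- dilate_disk(matrix(as.integer(occupied > 0), size, size), 2L)
  for (try in seq_len(20L)) {
    r1 <- runif(1, 1.5, 3); r2 <- runif(1, 1.5, 3)
    e <- render_ellipse(size, runif(1, 1 + r1, size - r1),
                        runif(1, 1 + r2, size - r2), r1, r2, runif(1, 0, pi))
    if (sum(e) > 0 && !any(e == 1L & occ_dil == 1L)) return(which(e == 1L))
  }
  NULL
}

#' Generate a full synthetic dataset with corrupted annotations
#'
#' Builds `n_train + n_val + n_test` phantoms whose annotations pass through
#' the corruption model, plus `n_gold` pristine gold-standard phantoms whose
#' annotations equal the ground truth exactly. Every instance keeps its
#' pristine ground truth in `gt_masks` for oracle scoring. Optionally
#' writes the on-disk layout (images, masks, manifest, corruption log).
#'
#' @param n_train,n_val,n_test,n_gold Partition sizes.
#' @param pcfg A [phantom_config()].
#' @param ccfg A [corruption_config()]; pass probabilities of 0 for pristine
#'   training annotations.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param dir Optional output directory.
#' @return A list of class `synthetic_dataset`: `split` (a
#'   [dataset_split()]), `corruption_log` (data frame with an `id` column).
#' @export
generate_dataset <- function(n_train, n_val, n_test, n_gold = 1L,
                             pcfg = phantom_config(),
                             ccfg = corruption_config(), seed = 1L,
                             dir = NULL) {
  counts <- c(train = n_train, validation = n_val, test = n_test, gold = n_gold)
  if (any(counts < 0)) stop_contract("partition counts must be >= 0")
  parts <- list(train = list(), validation = list(), test = list(), gold = list())
  logs <- list()
  k <- 0L
  for (part in names(counts)) {
    for (i in seq_len(counts[[part]])) {
      k <- k + 1L
      id <- sprintf("%s_%03d", part, i)
      inst <- generate_phantom(pcfg, seed = seed * 10000L + k, id = id)
      if (part != "gold") {
        cor <- corrupt_annotations(inst$masks, ccfg, seed = seed * 10000L + 5000L + k)
        inst <- annotated_instance(inst$image, cor$masks, id,
                                   gt_masks = inst$gt_masks)
        if (nrow(cor$log)) {
          cor$log$id <- id
          logs[[length(logs) + 1L]] <- cor$log
        }
      }
      parts[[part]][[i]] <- inst
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(type = character(0), class = character(0),
               component = integer(0), n_pixels = integer(0),
               pixels = character(0), id = character(0),
               stringsAsFactors = FALSE)
  split <- dataset_split(parts$train, parts$validation, parts$test, parts$gold)
  out <- structure(list(split = split, corruption_log = log),
                   class = "synthetic_dataset")
  if (!is.null(dir)) {
    for (part in names(split)) {
      pdir <- file.path(dir, part)
      for (inst in split[[part]]) write_instance(inst, pdir)
    }
    gt_dir <- file.path(dir, "ground_truth")
    for (part in names(split)) {
      for (inst in split[[part]]) {
        gt <- annotated_instance(inst$image, inst$gt_masks, inst$id)
        write_instance(gt, gt_dir)
      }
    }
    write_manifest(split, dir)
    write.csv(log, file.path(dir, "corruption_log.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  print(x$split)
  comp <- table(x$corruption_log$type)
  cat(sprintf("injected errors: %s\n",
              paste(sprintf("%s=%d", names(comp), comp), collapse = ", ")))
  invisible(x)
}
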
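#' Connected-component labeling by union-find
#'
#' Two-pass labeling built on a disjoint-set forest with path compression
#' and union by size. The first pass scans the mask in raster order,
#' assigning provisional labels and unioning each foreground pixel with its
#' already-visited neighbours (west and north for 4-connectivity, plus the
#' two upper diagonals for 8-connectivity); the second pass resolves roots
#' and renumbers components 1..n in raster order of their first pixel, so
#' the labeling is fully deterministic.
#'
#' @param mask Binary 0/1 matrix.
#' @param connectivity 4 or 8 (default 8 — thin diagonal vessels stay
#'   connected under 8-connectivity).
#' @return A list of class `component_labeling`: `label_map` (integer
#'   matrix, 0 = background), `n_components`, and `component_sizes`.
#' @export
connected_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop_contract("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  parent <- integer(0)
  size <- integer(0)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {  # path compression
      nxt <- parent[x]; parent[x] <<- root; x <- nxt
    }
    root
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra == rb) return(invisible(NULL))
    if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }  # union by size
    parent[rb] <<- ra
    size[ra] <<- size[ra] + size[rb]
    invisible(NULL)
  }
  prov <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (mask[r, c] == 0L) next
      neighbours <- integer(0)
      if (c > 1L && prov[r, c - 1L] > 0L) neighbours <- c(neighbours, prov[r, c - 1L])
      if (r > 1L && prov[r - 1L, c] > 0L) neighbours <- c(neighbours, prov[r - 1L, c])
      if (connectivity == 8L && r > 1L) {
        if (c > 1L && prov[r - 1L, c - 1L] > 0L) neighbours <- c(neighbours, prov[r - 1L, c - 1L])
        if (c < w && prov[r - 1L, c + 1L] > 0L) neighbours <- c(neighbours, prov[r - 1L, c + 1L])
      }
      if (length(neighbours) == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        size[length(size) + 1L] <- 1L
        prov[r, c] <- length(parent)
      } else {
        lab <- neighbours[1L]
        prov[r, c] <- lab
        size[find(lab)] <- size[find(lab)] + 1L
        for (nb in neighbours[-1L]) union(lab, nb)
      }
    }
  }
  # second pass: renumber roots in raster order of first occurrence.
  # raster order here is row-major (row by row, left to right).
  label_map <- matrix(0L, h, w)
  root_to_final <- integer(length(parent))
  n_final <- 0L
  sizes <- integer(0)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (prov[r, c] == 0L) next
      root <- find(prov[r, c])
      if (root_to_final[root] == 0L) {
        n_final <- n_final + 1L
        root_to_final[root] <- n_final
        sizes[n_final] <- 0L
      }
      lab <- root_to_final[root]
      label_map[r, c] <- lab
      sizes[lab] <- sizes[lab] + 1L
    }
  }
  structure(list(label_map = label_map, n_components = n_final,
                 component_sizes = sizes),
            class = "component_labeling")
}

#' @export
print.component_labeling <- function(x, ...) {
  cat(sprintf("<component_labeling> %d component(s); sizes: %s\n",
              x$n_components, paste(x$component_sizes, collapse = ", ")))
  invisible(x)
}

#' Locate strictly-missing labels
#'
#' Returns the connected components of `source` whose pixel sets share
#' *zero* pixels with the foreground of `reference` — the strict
#' disjointness rule: a component overlapping the reference by even a
#' single pixel is an overlapped label, not a missing one, and is excluded.
#'
#' @param source Binary mask whose components are tested (e.g. the network
#'   prediction when recovering labels missing from an annotation).
#' @param reference Binary mask defining the existing labels.
#' @param connectivity 4 or 8.
#' @return A `component_labeling` whose `label_map` keeps only the strictly
#'   disjoint components of `source`, renumbered 1..n in raster order.
#' @export
find_missing_labels <- function(source, reference, connectivity = 8L) {
  assert_mask(source, "source"); assert_mask(reference, "reference")
  assert_same_shape(source, reference, "find_missing_labels masks")
  comp <- connected_components(source, connectivity)
  if (comp$n_components == 0L) return(comp)
  overlap_by_comp <- tapply(reference[comp$label_map > 0L],
                            comp$label_map[comp$label_map > 0L], sum)
  keep <- as.integer(names(overlap_by_comp))[overlap_by_comp == 0]
  relabel <- integer(comp$n_components)
  relabel[sort(keep)] <- seq_along(keep)
  label_map <- matrix(0L, nrow(source), ncol(source))
  sel <- comp$label_map > 0L & comp$label_map %in% keep
  label_map[sel] <- relabel[comp$label_map[sel]]
  structure(list(label_map = label_map, n_components = length(keep),
                 component_sizes = comp$component_sizes[sort(keep)]),
            class = "component_labeling")
}

#' Fuse an annotation mask with a binarized prediction
#'
#' The three fusion strategies for repairing annotations with network
#' predictions:
#' \describe{
#'   \item{`"union"` (a)}{pixelwise OR of annotation and prediction — keeps
#'     every label from both, including each side's errors.}
#'   \item{`"annotation_primary"` (b)}{the annotation, plus the prediction
#'     components strictly disjoint from it — missing labels located from
#'     the predictions; overlapped label boundaries stay as annotated.}
#'   \item{`"prediction_primary"` (c)}{the prediction, plus the annotation
#'     components strictly disjoint from it — the mirror image, with
#'     overlapped boundaries taken from the prediction.}
#' }
#'
#' @param anno Binary annotation mask.
#' @param pred_binary Binary mask obtained by thresholding the network's
#'   probability map (see [binarize()]).
#' @param strategy `"union"`, `"annotation_primary"` or
#'   `"prediction_primary"`.
#' @param connectivity 4 or 8.
#' @return The fused binary mask.
#' @export
fuse_masks <- function(anno, pred_binary,
                       strategy = c("annotation_primary", "union",
                                    "prediction_primary"),
                       connectivity = 8L) {
  strategy <- match.arg(strategy)
  assert_mask(anno, "anno"); assert_mask(pred_binary, "pred_binary")
  assert_same_shape(anno, pred_binary, "fuse_masks inputs")
  if (strategy == "union") {
    return(matrix(as.integer(anno | pred_binary), nrow(anno), ncol(anno)))
  }
  if (strategy == "annotation_primary") {
    base <- anno; donor <- pred_binary
  } else {
    base <- pred_binary; donor <- anno
  }
  missing <- find_missing_labels(donor, base, connectivity)
  matrix(as.integer(base | (missing$label_map > 0L)), nrow(anno), ncol(anno))
}

#' Binarize a probability map
#'
#' @param p Numeric matrix of probabilities.
#' @param threshold Default 0.5.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(p, threshold = 0.5) {
  matrix(as.integer(p >= threshold), nrow(p), ncol(p))
}

#' Select (instance, class) pairs eligible for fusion
#'
#' Fusion only runs when the network is demonstrably good: the test-set
#' mean DC must reach `gate_threshold` (default 0.90) for *every* class —
#' otherwise no fusion action occurs at all. When the gate passes, the
#' candidates are the training (instance, class) pairs whose per-instance
#' DC falls below `candidate_threshold` (default 0.90): the instances the
#' network disagrees with, where the disagreement is more likely an
#' annotation error than a network error.
#'
#' @param per_instance_dc Numeric matrix, instances x classes (columns named
#'   as in [segmentation_classes()]), of training-set hard DCs.
#' @param test_mean_dc Named numeric vector of test-set mean DC per class.
#' @param candidate_threshold,gate_threshold Defaults 0.90.
#' @return A list with `gate_passed` (logical) and `candidates` (data frame
#'   with columns `instance` (row index) and `class`; empty if the gate
#'   fails or no DC is below threshold).
#' @export
select_fusion_candidates <- function(per_instance_dc, test_mean_dc,
                                     candidate_threshold = 0.90,
                                     gate_threshold = 0.90) {
  classes <- segmentation_classes()
  if (!all(classes %in% colnames(per_instance_dc)) ||
      !all(classes %in% names(test_mean_dc))) {
    stop_contract("DC entries missing for some class")
  }
  if (anyNA(per_instance_dc) || anyNA(test_mean_dc)) {
    stop_contract("DC entries contain missing values")
  }
  empty <- data.frame(instance = integer(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (any(test_mean_dc[classes] < gate_threshold)) {
    return(list(gate_passed = FALSE, candidates = empty))
  }
  rows <- lapply(classes, function(cl) {
    idx <- which(per_instance_dc[, cl] < candidate_threshold)
    if (length(idx) == 0L) return(NULL)
    data.frame(instance = idx, class = cl, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  list(gate_passed = TRUE, candidates = rows %||% empty)
}

#' Apply fusion to the selected candidates of a training set
#'
#' Replaces each candidate (instance, class) annotation mask by
#' [fuse_masks()] of the current mask with the binarized prediction;
#' non-candidate masks and instances are untouched. Fused instances get
#' provenance `"fused"`.
#'
#' @param train_set List of [annotated_instance()] objects.
#' @param predictions List (same order) of per-class probability maps.
#' @param candidates Data frame from [select_fusion_candidates()].
#' @param strategy Fusion strategy, see [fuse_masks()].
#' @param threshold Prediction binarization threshold, default 0.5.
#' @param connectivity 4 or 8.
#' @return A list with the updated `train_set` and a `report` data frame
#'   (instance id, class, components recovered, pixels added, strategy).
#' @export
apply_fusion <- function(train_set, predictions, candidates,
                         strategy = "annotation_primary", threshold = 0.5,
                         connectivity = 8L) {
  report <- data.frame(id = character(0), class = character(0),
                       n_components_added = integer(0),
                       pixels_added = integer(0), strategy = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(candidates) > 0 &&
      max(candidates$instance) > length(predictions)) {
    stop_contract("predictions missing for some candidate instance")
  }
  for (k in seq_len(nrow(candidates))) {
    i <- candidates$instance[k]
    cl <- candidates$class[k]
    inst <- train_set[[i]]
    anno <- inst$masks[[cl]]
    pred <- binarize(predictions[[i]][[cl]], threshold)
    fused <- fuse_masks(anno, pred, strategy, connectivity)
    base <- if (strategy == "prediction_primary") pred else anno
    added <- matrix(as.integer(fused == 1L & base == 0L), nrow(fused), ncol(fused))
    inst$masks[[cl]] <- fused
    inst$provenance <- "fused"
    train_set[[i]] <- inst
    report <- rbind(report, data.frame(
      id = inst$id, class = cl,
      n_components_added = connected_components(added, connectivity)$n_components,
      pixels_added = sum(added), strategy = strategy,
      stringsAsFactors = FALSE))
  }
  list(train_set = train_set, report = report)
}
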
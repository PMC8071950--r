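#' Segmentation classes handled by the framework
#'
#' The two tissue classes segmented jointly by the network: neuronal cell
#' bodies ("soma", dark gray in MOST imagery) and blood vessels ("vessel",
#' bright white). Class order is fixed throughout the package.
#'
#' @return Character vector `c("soma", "vessel")`.
#' @export
segmentation_classes <- function() c("soma", "vessel")

#' Create an annotated training instance
#'
#' Bundles one grayscale image with one binary annotation mask per class.
#' Images are plain numeric matrices indexed `[row, column]` with the origin
#' at the top-left; raw images hold 8-bit integers in 0--255, preprocessed
#' images hold reals in \[0, 1\]. Masks are 0/1 integer matrices of the same
#' shape (0 = background). On disk the foreground of a mask is stored as 255.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param masks Named list of 0/1 integer matrices, one per class in
#'   [segmentation_classes()], each the same shape as `image`.
#' @param id Stable instance identifier, unique within a dataset.
#' @param provenance One of `"original"`, `"augmented"`, `"fused"`.
#' @param gt_masks Optional named list of pristine ground-truth masks kept
#'   alongside corrupted annotations for oracle scoring (synthetic data only).
#' @return An object of class `annotated_instance`.
#' @export
annotated_instance <- function(image, masks, id,
                               provenance = c("original", "augmented", "fused"),
                               gt_masks = NULL) {
  provenance <- match.arg(provenance)
  if (!is.matrix(image) || nrow(image) < 1L || ncol(image) < 1L) {
    stop_contract("image must be a matrix with height, width >= 1")
  }
  classes <- segmentation_classes()
  if (!is.list(masks) || !setequal(names(masks), classes)) {
    stop_contract("instance '%s' needs exactly one mask per class (%s)",
                  id, paste(classes, collapse = ", "))
  }
  masks <- masks[classes]
  for (cl in classes) {
    assert_mask(masks[[cl]], sprintf("mask '%s' of instance '%s'", cl, id))
    if (!identical(dim(masks[[cl]]), dim(image))) {
      stop_contract("mask '%s' of instance '%s' (%dx%d) does not match image (%dx%d)",
                    cl, id, nrow(masks[[cl]]), ncol(masks[[cl]]),
                    nrow(image), ncol(image))
    }
  }
  structure(list(image = image, masks = masks, id = as.character(id),
                 provenance = provenance, gt_masks = gt_masks),
            class = "annotated_instance")
}

#' @export
print.annotated_instance <- function(x, ...) {
  cat(sprintf("<annotated_instance '%s'> %dx%d, %s; foreground px: %s\n",
              x$id, nrow(x$image), ncol(x$image), x$provenance,
              paste(sprintf("%s=%d", names(x$masks),
                            vapply(x$masks, sum, 0L)), collapse = ", ")))
  invisible(x)
}

#' Create a dataset split
#'
#' Partitions a dataset into training, validation, test and gold-standard
#' subsets. The gold partition is an independent, expert-quality set used
#' exclusively for reporting and final-model selection; it must never enter
#' training, checkpoint selection, fusion or weight updates.
#'
#' @param train,validation,test,gold Lists of [annotated_instance()] objects.
#'   Instance ids must be unique across all four partitions.
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(train, validation, test, gold = list()) {
  parts <- list(train = train, validation = validation, test = test, gold = gold)
  ids <- unlist(lapply(parts, function(p) vapply(p, `[[`, "", "id")))
  if (anyDuplicated(ids)) {
    stop_contract("duplicate instance id across partitions: '%s'",
                  ids[duplicated(ids)][1L])
  }
  structure(parts, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d validation=%d test=%d gold=%d\n",
              length(x$train), length(x$validation), length(x$test),
              length(x$gold)))
  invisible(x)
}

instance_ids <- function(instances) vapply(instances, `[[`, "", "id")
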
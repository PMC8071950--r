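#' Network architecture configuration
#'
#' Describes the two-head encoder-decoder: a contracting path of `depth`
#' levels (two 3x3 convolutions + ReLU per level, batch normalization
#' immediately before each 2x2 max-pooling), a two-convolution bottleneck,
#' and an expanding path where each stage applies dropout immediately
#' before nearest-neighbour upsampling, concatenates the skip connection
#' from the matching encoder level, and applies two further convolutions.
#' A 1x1 convolution with sigmoid activation emits one probability map per
#' class, so a single forward pass segments both somata and vessels.
#'
#' @param input_size Image side in pixels; must be divisible by
#'   `2^depth`. Default 512 (the full-scale configuration); use 64 with
#'   `depth = 2`, `base_filters = 8` for a desk-scale network of under
#'   100,000 parameters.
#' @param depth Number of down/up levels, default 4.
#' @param base_filters Channels at the top level, doubling per level,
#'   default 64.
#' @param dropout_rate Dropout before each upsampling stage, default 0.5.
#' @param classes Ordered class labels; fixed to soma, vessel.
#' @return A list of class `network_config`.
#' @export
network_config <- function(input_size = 512L, depth = 4L, base_filters = 64L,
                           dropout_rate = 0.5,
                           classes = segmentation_classes()) {
  if (input_size %% 2^depth != 0) {
    stop_contract("input_size (%d) must be divisible by 2^depth (%d)",
                  input_size, 2^depth)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_contract("dropout_rate must lie in [0, 1)")
  }
  if (!identical(classes, segmentation_classes())) {
    stop_contract("classes must be %s (in order)",
                  paste(segmentation_classes(), collapse = ", "))
  }
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate, classes = classes),
            class = "network_config")
}

#' Training configuration
#'
#' @param epochs Training epochs per boosting iteration, default 3000.
#' @param learning_rate Constant Adam learning rate, default 5e-5.
#' @param optimizer Only `"adam"` is provided.
#' @param batch_size Minibatch size, default 8 (batch-normalization
#'   statistics are computed over the minibatch).
#' @param seed Integer seed driving weight initialization, shuffling and
#'   dropout.
#' @param eps Soft-Dice smoothing inside the loss, default 1.
#' @param tau Clamp on each DC before the logarithm, default 1e-7.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 3000L, learning_rate = 5e-5,
                            optimizer = "adam", batch_size = 8L, seed = 1L,
                            eps = 1, tau = 1e-7) {
  if (epochs < 1L) stop_contract("epochs must be >= 1")
  if (learning_rate <= 0) stop_contract("learning_rate must be > 0")
  if (optimizer != "adam") stop_contract("only the adam optimizer is available")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), eps = eps, tau = tau),
            class = "training_config")
}

#' Build an (untrained) two-head segmentation network
#'
#' Initializes all convolution weights with seeded He-normal draws; batch
#' normalization starts at identity. The untrained network already maps any
#' valid input to finite probability maps in \[0, 1\].
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `unet_model` with fields `params` (parameter
#'   state), `config`, and (after training) `history`, `best`.
#' @export
build_network <- function(config, seed = 1L) {
  params <- cnn_init(config$depth, config$base_filters, config$dropout_rate,
                     as.integer(seed))
  structure(list(params = params, config = config, history = NULL, best = NULL),
            class = "unet_model")
}

#' Number of trainable parameters of a model
#'
#' @param model A `unet_model`.
#' @return Integer count (convolution weights and biases, BN scale/shift).
#' @export
n_parameters <- function(model) {
  p <- model$params
  trainable <- grepl("_W_|_b_|^b[12]_|^head_|bn_gamma|bn_beta", names(p)) &
    !grepl("rmean|rvar|depth|base_filters|dropout", names(p))
  sum(vapply(p[trainable], length, 0L))
}

#' Train the network with per-instance sample weights
#'
#' Minimizes the Dice-logarithmic loss with Adam. Instance `i`'s loss terms
#' are scaled by `m * w[i, class]` on each matching term and by the mean of
#' the two class factors on the cross terms, so a uniform weight table
#' (`w = 1/m` everywhere) reproduces unweighted training exactly. After
#' every epoch the unweighted validation loss is recorded (inference mode:
#' running BN statistics, no dropout) and the parameters achieving the
#' lowest validation loss so far are snapshotted — ties keep the earliest
#' epoch.
#'
#' @param model A `unet_model` from [build_network()].
#' @param train_set List of [annotated_instance()] objects with images
#'   in \[0, 1\].
#' @param weights Sample-weight table ([init_weights()]); one row per
#'   training instance, each class column summing to 1.
#' @param val_set Validation instances.
#' @param tcfg A [training_config()].
#' @return The model with updated `params` (final epoch), `best`
#'   (`$params`, `$epoch`), and `history` (data frame: epoch, train_loss,
#'   val_loss).
#' @export
train_network <- function(model, train_set, weights, val_set, tcfg) {
  validate_weights(weights)
  if (nrow(weights) != length(train_set)) {
    stop_contract("weight table has %d rows for %d training instances",
                  nrow(weights), length(train_set))
  }
  get_imgs <- function(set) lapply(set, function(x) check_input(model$config, x$image))
  get_masks <- function(set, cl) lapply(set, function(x) x$masks[[cl]] * 1.0)
  fit <- cnn_train(model$params,
                   get_imgs(train_set),
                   get_masks(train_set, "soma"), get_masks(train_set, "vessel"),
                   weights[, segmentation_classes(), drop = FALSE],
                   get_imgs(val_set),
                   get_masks(val_set, "soma"), get_masks(val_set, "vessel"),
                   tcfg$epochs, tcfg$learning_rate, tcfg$batch_size,
                   tcfg$seed, tcfg$eps, tcfg$tau)
  model$params <- fit$final_params
  model$best <- list(params = fit$best_params, epoch = fit$best_epoch)
  model$history <- data.frame(epoch = seq_len(tcfg$epochs),
                              train_loss = as.numeric(fit$train_loss),
                              val_loss = as.numeric(fit$val_loss))
  model
}

check_input <- function(config, image) {
  if (!is.matrix(image) || nrow(image) != config$input_size ||
      ncol(image) != config$input_size) {
    stop_contract("input must be %dx%d for this network configuration",
                  config$input_size, config$input_size)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop_contract("input images must be preprocessed to [0, 1]")
  }
  image
}

#' Epoch index of the best checkpoint
#'
#' Argmin of the per-epoch validation loss; ties resolve to the earliest
#' epoch.
#'
#' @param model A trained `unet_model`.
#' @return Integer epoch index (1-based).
#' @export
select_best_checkpoint <- function(model) {
  if (is.null(model$history) || nrow(model$history) == 0L) {
    stop_contract("model has no training history")
  }
  which.min(model$history$val_loss)
}

#' Predict per-class probability maps
#'
#' One forward pass yields both class maps simultaneously. By default the
#' best-validation-loss checkpoint is used when available.
#'
#' @param object A `unet_model`.
#' @param images A single image matrix in \[0, 1\], or a list of them.
#' @param checkpoint `"best"` (default; falls back to final if untrained)
#'   or `"final"`.
#' @param ... Unused.
#' @return For a single image, a named list of probability-map matrices
#'   (`soma`, `vessel`); for a list input, a list of such lists in input
#'   order.
#' @export
predict.unet_model <- function(object, images, checkpoint = c("best", "final"),
                               ...) {
  checkpoint <- match.arg(checkpoint)
  single <- is.matrix(images)
  if (single) images <- list(images)
  images <- lapply(images, function(x) check_input(object$config, x))
  params <- if (checkpoint == "best" && !is.null(object$best)) {
    object$best$params
  } else {
    object$params
  }
  out <- cnn_predict(params, images)
  if (single) out[[1L]] else out
}

#' Inference-mode Dice-logarithmic loss of a model on a set
#'
#' Evaluates the per-instance weighted loss with the current parameters
#' (running BN statistics, no dropout). Useful for inspecting how sample
#' weights scale each instance's contribution to the epoch loss.
#'
#' @param model A `unet_model`.
#' @param instances Instances with images in \[0, 1\].
#' @param weights Sample-weight table; defaults to uniform.
#' @param tcfg A [training_config()] supplying `eps`/`tau`.
#' @param checkpoint `"final"` (default) or `"best"`.
#' @return A list: `total` (numeric vector of per-instance totals),
#'   `terms` (matrix m x 4: soma-match, vessel-match, soma-cross,
#'   vessel-cross), `mean` (scalar mean loss).
#' @export
evaluate_loss <- function(model, instances, weights = NULL,
                          tcfg = training_config(),
                          checkpoint = c("final", "best")) {
  checkpoint <- match.arg(checkpoint)
  m <- length(instances)
  if (is.null(weights)) weights <- init_weights(m)
  validate_weights(weights)
  params <- if (checkpoint == "best" && !is.null(model$best)) {
    model$best$params
  } else {
    model$params
  }
  res <- cnn_eval_loss(params,
                       lapply(instances, function(x) check_input(model$config, x$image)),
                       lapply(instances, function(x) x$masks$soma * 1.0),
                       lapply(instances, function(x) x$masks$vessel * 1.0),
                       weights[, segmentation_classes(), drop = FALSE],
                       tcfg$eps, tcfg$tau)
  colnames(res$terms) <- c("soma_match", "vessel_match", "soma_cross",
                           "vessel_cross")
  list(total = as.numeric(res$total), terms = res$terms,
       mean = mean(as.numeric(res$total)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %dx%d input, depth %d, base %d; %s parameters%s\n",
              x$config$input_size, x$config$input_size, x$config$depth,
              x$config$base_filters, format(n_parameters(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf("; trained %d epochs, best epoch %d",
                        nrow(x$history), x$best$epoch)))
  invisible(x)
}
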
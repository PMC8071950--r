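#' Initialize a sample-weight table
#'
#' Every training instance starts with the same weight `1/m` for both
#' classes, so the first training round is exactly unweighted.
#'
#' @param m Number of training instances (>= 1).
#' @return An `m x 2` matrix with columns named by
#'   [segmentation_classes()]; each column sums to 1.
#' @export
init_weights <- function(m) {
  if (m < 1L) stop_contract("need at least one instance")
  w <- matrix(1 / m, nrow = m, ncol = 2L,
              dimnames = list(NULL, segmentation_classes()))
  w
}

validate_weights <- function(weights) {
  classes <- segmentation_classes()
  if (!is.matrix(weights) || !all(classes %in% colnames(weights))) {
    stop_contract("weights must be a matrix with columns %s",
                  paste(classes, collapse = ", "))
  }
  if (any(weights < 0)) stop_contract("weights must be nonnegative")
  sums <- colSums(weights[, classes, drop = FALSE])
  if (any(abs(sums - 1) > 1e-9)) {
    stop_contract("each class column of the weight table must sum to 1")
  }
  invisible(weights)
}

#' Weighted error rate of a training round
#'
#' The weight mass of the instances whose Dice coefficient for class `j`
#' falls strictly below the boosting threshold `delta`, divided by the
#' total weight mass:
#' \deqn{Err_j = \sum_{i: DC_{ij} < \delta} w_{ij} / \sum_i w_{ij}}
#'
#' @param weights Sample-weight table from [init_weights()] /
#'   [update_weights()].
#' @param dcs Numeric vector of per-instance DCs for class `class`.
#' @param class `"soma"` or `"vessel"`.
#' @param delta Boosting DC threshold, default 0.97.
#' @return `Err_j` in \[0, 1\].
#' @export
weighted_error <- function(weights, dcs, class, delta = 0.97) {
  validate_weights(weights)
  if (length(dcs) != nrow(weights) || anyNA(dcs)) {
    stop_contract("need one DC per instance for class '%s'", class)
  }
  w <- weights[, class]
  sum(w[dcs < delta]) / sum(w)
}

#' AdaBoost-style sample-weight update for one class
#'
#' If the weighted error rate lies in (0, 0.5) — the network is better than
#' random but not perfect on the weighted training set — the weights of the
#' below-threshold instances are multiplied by
#' `exp(0.5 * log((1 - Err) / Err)) = sqrt((1 - Err) / Err) > 1` and the
#' column is renormalized to sum 1. Otherwise (`Err = 0` or `Err >= 0.5`)
#' the column is returned bit-identical. The other class's column is never
#' touched, so updates for the two classes commute.
#'
#' @inheritParams weighted_error
#' @return The updated weight table.
#' @export
update_weights <- function(weights, dcs, class, delta = 0.97) {
  validate_weights(weights)
  err <- weighted_error(weights, dcs, class, delta)
  if (err <= 0 || err >= 0.5) return(weights)
  mult <- exp(0.5 * log((1 - err) / err))
  w <- weights[, class]
  w[dcs < delta] <- w[dcs < delta] * mult
  weights[, class] <- w / sum(w)
  weights
}

#' Boosting configuration
#'
#' @param delta Per-instance DC threshold below which an instance counts as
#'   hard and is up-weighted, default 0.97 for both classes.
#' @param max_iterations Number of boosting rounds, default 10.
#' @param strategy Fusion strategy, default `"annotation_primary"` (b).
#' @param gate_threshold,candidate_threshold Fusion gates, default 0.90.
#' @param final_rule `"latest"` or `"best_on_gold"`.
#' @param goal_gold_dc Optional early-stop goal: when the gold-set mean DC
#'   of every class reaches this value the loop stops. Default `NULL`
#'   (run all iterations).
#' @param threshold Prediction binarization threshold, default 0.5.
#' @return A list of class `boosting_config`.
#' @export
boosting_config <- function(delta = 0.97, max_iterations = 10L,
                            strategy = "annotation_primary",
                            gate_threshold = 0.90, candidate_threshold = 0.90,
                            final_rule = c("latest", "best_on_gold"),
                            goal_gold_dc = NULL, threshold = 0.5) {
  if (delta <= 0 || delta > 1) stop_contract("delta must lie in (0, 1]")
  if (max_iterations < 1L) stop_contract("max_iterations must be >= 1")
  structure(list(delta = delta, max_iterations = as.integer(max_iterations),
                 strategy = strategy, gate_threshold = gate_threshold,
                 candidate_threshold = candidate_threshold,
                 final_rule = match.arg(final_rule),
                 goal_gold_dc = goal_gold_dc, threshold = threshold),
            class = "boosting_config")
}

#' Run the full fusion + boosting loop
#'
#' Each iteration: (i) build a freshly initialized network (iteration-indexed
#' seed) and train it with the current sample weights; (ii) select the best
#' checkpoint by validation loss; (iii) evaluate per-instance training DCs
#' and mean test/gold DCs per class; (iv) when the test-set gate passes,
#' fuse the below-threshold training annotations with the predictions
#' (the fused set is what the *next* iteration trains on); (v) update the
#' sample weights per class from the pre-fusion training DCs; (vi) log
#' everything. The gold partition is touched only for reporting and final
#' selection, never for training, checkpoint selection, fusion or weight
#' updates.
#'
#' @param split A [dataset_split()] with a nonempty gold partition. Images
#'   may be raw 8-bit (preprocessed internally) or already in \[0, 1\].
#' @param ncfg A [network_config()].
#' @param tcfg A [training_config()].
#' @param bcfg A [boosting_config()].
#' @param run_dir Optional directory; per-iteration weight tables, metrics,
#'   fusion reports and checkpoints are persisted there.
#' @param verbose Print one line per iteration.
#' @return A list of class `boosting_state`: `iterations` (list of
#'   per-iteration records), `final` (iteration index of the selected final
#'   network), `metrics` (data frame: iteration, partition, class, mean_dc),
#'   `weights` (final table).
#' @export
run_boosting <- function(split, ncfg, tcfg, bcfg = boosting_config(),
                         run_dir = NULL, verbose = FALSE) {
  if (length(split$gold) == 0L) stop_contract("gold partition must be nonempty")
  classes <- segmentation_classes()
  train_set <- lapply(split$train, preprocess_instance)
  val_set <- lapply(split$validation, preprocess_instance)
  test_set <- lapply(split$test, preprocess_instance)
  gold_set <- lapply(split$gold, preprocess_instance)
  m <- length(train_set)
  weights <- init_weights(m)
  iterations <- list()
  if (!is.null(run_dir)) dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

  for (t in seq_len(bcfg$max_iterations)) {
    tcfg_t <- tcfg
    tcfg_t$seed <- tcfg$seed + t  # fresh, iteration-indexed initialization
    model <- build_network(ncfg)
    model <- train_network(model, train_set, weights, val_set, tcfg_t)
    best_epoch <- select_best_checkpoint(model)

    preds_train <- predict_instances(model, train_set)
    dc_train <- per_instance_dc(train_set, preds_train, bcfg$threshold)
    test_mean <- vapply(classes, function(cl)
      mean_dice(test_set, predict_instances(model, test_set), cl, bcfg$threshold), 0)
    gold_mean <- vapply(classes, function(cl)
      mean_dice(gold_set, predict_instances(model, gold_set), cl, bcfg$threshold), 0)

    sel <- select_fusion_candidates(dc_train, test_mean,
                                    bcfg$candidate_threshold, bcfg$gate_threshold)
    fusion <- apply_fusion(train_set, preds_train, sel$candidates,
                           bcfg$strategy, bcfg$threshold)

    err <- vapply(classes, function(cl)
      weighted_error(weights, dc_train[, cl], cl, bcfg$delta), 0)
    new_weights <- weights
    for (cl in classes) {  # pre-fusion DCs drive the update
      new_weights <- update_weights(new_weights, dc_train[, cl], cl, bcfg$delta)
    }

    record <- list(iteration = t, err = err, weights = new_weights,
                   best_epoch = best_epoch, model = model,
                   train_dc = dc_train, test_mean_dc = test_mean,
                   gold_mean_dc = gold_mean, gate_passed = sel$gate_passed,
                   n_fused = nrow(fusion$report), fusion_report = fusion$report)
    iterations[[t]] <- record
    if (!is.null(run_dir)) persist_iteration(run_dir, record, fusion$train_set)
    if (verbose) {
      message(sprintf(
        "iter %d: Err=(%.3f, %.3f) test DC=(%.3f, %.3f) gold DC=(%.3f, %.3f) gate=%s fused=%d",
        t, err[1L], err[2L], test_mean[1L], test_mean[2L],
        gold_mean[1L], gold_mean[2L], sel$gate_passed, nrow(fusion$report)))
    }

    train_set <- fusion$train_set
    weights <- new_weights
    if (!is.null(bcfg$goal_gold_dc) && all(gold_mean >= bcfg$goal_gold_dc)) break
  }

  metrics <- do.call(rbind, lapply(iterations, function(it) {
    do.call(rbind, lapply(c(test = "test", gold = "gold"), function(part) {
      mdc <- if (part == "test") it$test_mean_dc else it$gold_mean_dc
      data.frame(iteration = it$iteration, partition = part,
                 class = classes, mean_dc = unname(mdc),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(metrics) <- NULL
  # running OLS trend of mean DC up to each iteration
  metrics$slope_so_far <- NA_real_
  for (part in unique(metrics$partition)) {
    for (cl in classes) {
      sel <- metrics$partition == part & metrics$class == cl
      series <- metrics$mean_dc[sel][order(metrics$iteration[sel])]
      metrics$slope_so_far[sel] <- vapply(seq_along(series), function(k) {
        if (k < 2L) NA_real_ else trend_slope(series[seq_len(k)])
      }, 0)
    }
  }
  state <- structure(list(iterations = iterations, metrics = metrics,
                          weights = weights, config = bcfg),
                     class = "boosting_state")
  state$final <- select_final_network(state, bcfg$final_rule)
  if (!is.null(run_dir)) {
    write.csv(metrics, file.path(run_dir, "metrics.csv"), row.names = FALSE)
  }
  state
}

preprocess_instance <- function(inst) {
  if (max(inst$image) > 1) {
    inst$image <- preprocess(inst$image)
  }
  inst
}

predict_instances <- function(model, instances) {
  predict(model, lapply(instances, `[[`, "image"))
}

per_instance_dc <- function(instances, predictions, threshold = 0.5) {
  classes <- segmentation_classes()
  dc <- matrix(NA_real_, length(instances), length(classes),
               dimnames = list(instance_ids(instances), classes))
  for (i in seq_along(instances)) {
    for (cl in classes) {
      dc[i, cl] <- dice_coefficient(instances[[i]]$masks[[cl]],
                                    binarize(predictions[[i]][[cl]], threshold))
    }
  }
  dc
}

persist_iteration <- function(run_dir, record, train_set = NULL) {
  tag <- sprintf("iter%02d", record$iteration)
  write.csv(as.data.frame(record$weights),
            file.path(run_dir, paste0(tag, "_weights.csv")), row.names = FALSE)
  write.csv(record$fusion_report,
            file.path(run_dir, paste0(tag, "_fusion.csv")), row.names = FALSE)
  write.csv(record$model$history,
            file.path(run_dir, paste0(tag, "_history.csv")), row.names = FALSE)
  saveRDS(record$model, file.path(run_dir, paste0(tag, "_checkpoint.rds")))
  # fused masks beside the run so every iteration's training set is
  # reconstructible from the originals plus these files
  if (!is.null(train_set) && nrow(record$fusion_report) > 0) {
    fdir <- file.path(run_dir, paste0(tag, "_fused"))
    dir.create(fdir, showWarnings = FALSE)
    ids <- instance_ids(train_set)
    for (k in seq_len(nrow(record$fusion_report))) {
      rid <- record$fusion_report$id[k]
      cl <- record$fusion_report$class[k]
      inst <- train_set[[match(rid, ids)]]
      EBImage::writeImage(
        EBImage::Image(t(inst$masks[[cl]])),
        file.path(fdir, sprintf("%s_%s_fused_%s.png", rid, cl, tag)))
    }
  }
}

#' Select the final network after boosting
#'
#' @param state A `boosting_state`.
#' @param rule `"latest"` (the last iteration's network) or
#'   `"best_on_gold"` (argmax of the gold-set mean DC averaged over
#'   classes; ties broken toward the latest iteration).
#' @return The iteration index of the selected network.
#' @export
select_final_network <- function(state, rule = c("latest", "best_on_gold")) {
  rule <- match.arg(rule)
  n <- length(state$iterations)
  if (n == 0L) stop_contract("boosting state has no completed iteration")
  if (rule == "latest") return(n)
  gold <- vapply(state$iterations, function(it) mean(it$gold_mean_dc), 0)
  max(which(gold == max(gold)))  # ties -> latest
}

#' @export
print.boosting_state <- function(x, ...) {
  cat(sprintf("<boosting_state> %d iteration(s); final = iteration %d\n",
              length(x$iterations), x$final))
  print(x$metrics)
  invisible(x)
}

#' Summarize a boosting run in the layout of a performance table
#'
#' One row per (partition, class): the final network's mean DC and the OLS
#' linear trend coefficient of mean DC across iterations.
#'
#' @param state A `boosting_state`.
#' @return A data frame with columns `partition`, `class`, `mean_dc`,
#'   `linear_coef`.
#' @export
summarize_boosting <- function(state) {
  classes <- segmentation_classes()
  final <- state$iterations[[state$final]]
  rows <- list()
  for (part in c("gold", "test")) {
    for (cl in classes) {
      series <- state$metrics$mean_dc[state$metrics$partition == part &
                                        state$metrics$class == cl]
      mdc <- if (part == "gold") final$gold_mean_dc[[cl]] else final$test_mean_dc[[cl]]
      rows[[length(rows) + 1L]] <- data.frame(
        partition = part, class = cl, mean_dc = mdc,
        linear_coef = if (length(series) >= 2L) trend_slope(series) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
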
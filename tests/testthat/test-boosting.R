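test_that("initial weights are uniform probability columns", {
  w <- init_weights(2400)
  expect_equal(dim(w), c(2400L, 2L))
  expect_true(all(w == 1 / 2400))
  expect_equal(colSums(w), c(soma = 1, vessel = 1))
  expect_equal(init_weights(1)[1, ], c(soma = 1, vessel = 1))
  expect_error(init_weights(0), "at least one")
  for (m in c(3, 17, 100)) expect_equal(unname(colSums(init_weights(m))), c(1, 1))
})

test_that("weighted error sums the weight mass below the threshold", {
  w <- init_weights(4)
  expect_equal(weighted_error(w, c(1, 1, 0.99, 0.98), "soma", delta = 0.97), 0)
  expect_equal(weighted_error(w, c(1, 1, 1, 0.9), "soma", delta = 0.97), 0.25)
  w2 <- cbind(soma = c(0.1, 0.2, 0.3, 0.4), vessel = rep(0.25, 4))
  expect_equal(weighted_error(w2, c(0.5, 1, 1, 0.6), "soma", delta = 0.97), 0.5)
  # the threshold comparison is strict
  expect_equal(weighted_error(w, rep(0.97, 4), "soma", delta = 0.97), 0)
  expect_error(weighted_error(w, c(1, 1), "soma"), "one DC per instance")
})

test_that("weight update applies the closed-form multiplier then renormalizes", {
  w <- init_weights(4)
  dcs <- c(1, 1, 1, 0.9)            # Err = 0.25, multiplier sqrt(3)
  up <- update_weights(w, dcs, "soma", delta = 0.97)
  k <- sqrt((1 - 0.25) / 0.25)
  expect_equal(unname(up[, "soma"]),
               c(0.25, 0.25, 0.25, 0.25 * k) / (0.75 + 0.25 * k),
               tolerance = 1e-12)
  expect_equal(unname(up[, "soma"]),
               c(0.2113248654, 0.2113248654, 0.2113248654, 0.3660254038),
               tolerance = 1e-9)
  # the vessel column is untouched
  expect_identical(up[, "vessel"], w[, "vessel"])

  # no-op branches are bit-identical
  expect_identical(update_weights(w, rep(1, 4), "soma"), w)      # Err = 0
  low <- c(0.5, 0.5, 0.5, 1)                                     # Err = 0.75
  expect_identical(update_weights(w, low, "soma"), w)
})

test_that("weighted-error and weight-update closed forms match brute force", {
  set.seed(1234)
  n_checked <- 0L
  for (trial in 1:1000) {
    m <- sample(2:40, 1)
    raw <- matrix(runif(2 * m, 0.01, 1), m, 2)
    w <- sweep(raw, 2, colSums(raw), "/")
    colnames(w) <- segmentation_classes()
    delta <- runif(1, 0.8, 0.99)
    # mostly-above-threshold DCs keep Err in (0, 0.5) often enough to
    # exercise the multiplicative branch, while leaving no-op cases too
    dcs <- ifelse(runif(m) < 0.75, runif(m, delta, 1), runif(m, 0.4, delta))
    cl <- sample(segmentation_classes(), 1)

    # brute force straight from the definitions
    err_bf <- sum(w[dcs < delta, cl]) / sum(w[, cl])
    expect_equal(weighted_error(w, dcs, cl, delta), err_bf, tolerance = 1e-12)

    up <- update_weights(w, dcs, cl, delta)
    if (err_bf > 0 && err_bf < 0.5) {
      mult <- exp(0.5 * log((1 - err_bf) / err_bf))
      bf <- w[, cl]
      bf[dcs < delta] <- bf[dcs < delta] * mult
      bf <- bf / sum(bf)
      expect_equal(unname(up[, cl]), unname(bf), tolerance = 1e-12)
      # post-normalization boosted/unboosted ratio equals sqrt((1-Err)/Err)
      if (any(dcs < delta) && any(dcs >= delta)) {
        i_b <- which(dcs < delta)[1L]
        i_u <- which(dcs >= delta)[1L]
        ratio <- unname((up[i_b, cl] / w[i_b, cl]) / (up[i_u, cl] / w[i_u, cl]))
        expect_equal(ratio, sqrt((1 - err_bf) / err_bf), tolerance = 1e-12)
        expect_gt(ratio, 1)
        n_checked <- n_checked + 1L
      }
    } else {
      expect_identical(up, w)
    }
    expect_equal(unname(colSums(up)), c(1, 1), tolerance = 1e-9)
    expect_true(all(up >= 0))
  }
  expect_gt(n_checked, 300L)  # the ratio branch was exercised often
})

test_that("per-class weight updates commute", {
  set.seed(77)
  for (k in 1:20) {
    m <- sample(3:20, 1)
    w <- init_weights(m)
    dc_s <- runif(m, 0.7, 1)
    dc_v <- runif(m, 0.7, 1)
    a <- update_weights(update_weights(w, dc_s, "soma"), dc_v, "vessel")
    b <- update_weights(update_weights(w, dc_v, "vessel"), dc_s, "soma")
    expect_identical(a, b)
  }
})

test_that("final-network selection follows the configured rule", {
  fake_state <- function(gold_means) {
    structure(list(iterations = lapply(seq_along(gold_means), function(i) {
      list(iteration = i, gold_mean_dc = c(soma = gold_means[i],
                                           vessel = gold_means[i]))
    })), class = "boosting_state")
  }
  st <- fake_state(c(0.80, 0.90, 0.85))
  expect_identical(select_final_network(st, "best_on_gold"), 2L)
  expect_identical(select_final_network(st, "latest"), 3L)
  expect_identical(select_final_network(fake_state(0.8), "best_on_gold"), 1L)
  # ties resolve to the latest iteration
  expect_identical(select_final_network(fake_state(c(0.9, 0.9)), "best_on_gold"), 2L)
  expect_error(select_final_network(fake_state(numeric(0))), "no completed")
})

test_that("a tiny boosting run persists a self-describing run directory", {
  run_dir <- withr::local_tempdir()
  ds <- generate_dataset(6, 2, 2, 2, seed = 14)
  ncfg <- network_config(input_size = 64, depth = 2, base_filters = 4)
  tcfg <- training_config(epochs = 3, learning_rate = 1e-3, batch_size = 3,
                          seed = 4)
  bcfg <- boosting_config(max_iterations = 2, final_rule = "best_on_gold")
  st <- run_boosting(ds$split, ncfg, tcfg, bcfg, run_dir = run_dir)
  expect_length(st$iterations, 2L)
  expect_true(st$final %in% 1:2)
  for (t in 1:2) {
    tag <- sprintf("iter%02d", t)
    expect_true(file.exists(file.path(run_dir, paste0(tag, "_weights.csv"))))
    expect_true(file.exists(file.path(run_dir, paste0(tag, "_checkpoint.rds"))))
    expect_true(file.exists(file.path(run_dir, paste0(tag, "_history.csv"))))
    w <- as.matrix(read.csv(file.path(run_dir, paste0(tag, "_weights.csv"))))
    expect_equal(unname(colSums(w)), c(1, 1), tolerance = 1e-9)
    hist <- read.csv(file.path(run_dir, paste0(tag, "_history.csv")))
    expect_identical(nrow(hist), 3L)
  }
  metrics <- read.csv(file.path(run_dir, "metrics.csv"))
  expect_identical(sort(unique(metrics$partition)), c("gold", "test"))
  expect_true("slope_so_far" %in% names(metrics))
  expect_true(all(is.na(metrics$slope_so_far[metrics$iteration == 1])))
  expect_true(all(is.finite(metrics$slope_so_far[metrics$iteration == 2])))
  # a reloaded checkpoint predicts identically to the in-memory model
  m2 <- readRDS(file.path(run_dir, "iter02_checkpoint.rds"))
  img <- preprocess(ds$split$gold[[1]]$image)
  expect_identical(predict(m2, img), predict(st$iterations[[2]]$model, img))
})
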
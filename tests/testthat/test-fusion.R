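test_that("diagonal touching splits under 4-connectivity and joins under 8", {
  m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_identical(connected_components(m, 8L)$n_components, 1L)
  expect_identical(connected_components(m, 4L)$n_components, 2L)
  expect_identical(connected_components(matrix(0L, 5, 5))$n_components, 0L)
  full <- connected_components(matrix(1L, 6, 7))
  expect_identical(full$n_components, 1L)
  expect_identical(full$component_sizes, 42L)
})

test_that("union-find labeling agrees with a flood-fill oracle on random masks", {
  set.seed(271)
  for (k in 1:100) {
    m <- random_mask(16, 16, p = runif(1, 0.2, 0.6))
    for (conn in c(4L, 8L)) {
      got <- connected_components(m, conn)
      want <- flood_fill_components(m, conn)
      expect_identical(got$n_components, want$n_components)
      expect_true(same_partition(got$label_map, want$label_map))
      # label invariants: 1..n with no gaps, sizes consistent
      if (got$n_components > 0) {
        expect_identical(sort(unique(got$label_map[got$label_map > 0])),
                         seq_len(got$n_components))
        expect_identical(as.integer(tabulate(got$label_map[got$label_map > 0])),
                         got$component_sizes)
      }
    }
  }
})

test_that("strictly-missing labels exclude any component overlapping the reference", {
  src <- matrix(0L, 8, 8)
  src[1:2, 1:2] <- 1L      # S1, will overlap the reference
  src[6:7, 6:7] <- 1L      # S2, disjoint
  ref <- matrix(0L, 8, 8); ref[2:4, 2:4] <- 1L
  got <- find_missing_labels(src, ref)
  expect_identical(got$n_components, 1L)
  expect_identical(which(got$label_map > 0L), which(blob(8, 8, 6, 6, 2, 2) == 1L))

  # a single shared pixel disqualifies a component
  ref1 <- matrix(0L, 8, 8); ref1[7, 7] <- 1L
  got1 <- find_missing_labels(src, ref1)
  expect_identical(got1$n_components, 1L)  # only S1 remains strictly disjoint
  expect_identical(which(got1$label_map > 0L), which(blob(8, 8, 1, 1, 2, 2) == 1L))

  expect_identical(find_missing_labels(matrix(0L, 4, 4),
                                       matrix(0L, 4, 4))$n_components, 0L)
})

test_that("the three fusion strategies follow their set algebra", {
  # anno: one component spanning rows 2-3, cols 2-4 (1-based)
  anno <- blob(8, 8, 2, 2, 2, 3)
  # pred: same region trimmed to cols 2-3, plus a disjoint comp at (6,6)-(7,7)
  pred <- blob(8, 8, 2, 2, 2, 2) + blob(8, 8, 6, 6, 2, 2)
  pred <- matrix(as.integer(pred > 0), 8, 8)

  fb <- fuse_masks(anno, pred, "annotation_primary")
  expect_identical(fb, matrix(as.integer((anno | blob(8, 8, 6, 6, 2, 2))), 8, 8))
  fc <- fuse_masks(anno, pred, "prediction_primary")
  expect_identical(fc, pred)  # anno's comp overlaps pred: nothing added
  fa <- fuse_masks(anno, pred, "union")
  expect_identical(fa, matrix(as.integer(anno | pred), 8, 8))

  # pred subset of anno: strategy (b) is a no-op
  sub <- blob(8, 8, 2, 2, 1, 2)
  expect_identical(fuse_masks(anno, sub, "annotation_primary"), anno)
})

test_that("fusion reproduces the textbook missing/fake label scene", {
  # ground truth: four labels; annotation misses label 3; prediction misses
  # label 4 and adds a fake label 5.
  gt <- list(l1 = blob(16, 16, 1, 1, 3, 3), l2 = blob(16, 16, 1, 12, 3, 3),
             l3 = blob(16, 16, 12, 1, 3, 3), l4 = blob(16, 16, 12, 12, 3, 3))
  all_of <- function(parts) {
    matrix(as.integer(Reduce(`|`, parts)), 16, 16)
  }
  anno <- all_of(gt[c("l1", "l2", "l4")])
  fake <- blob(16, 16, 7, 7, 2, 2)
  pred <- all_of(c(gt[c("l1", "l2", "l3")], list(fake)))

  fa <- fuse_masks(anno, pred, "union")
  expect_true(all(fa[fake == 1L] == 1L))  # union keeps the fake label
  fb <- fuse_masks(anno, pred, "annotation_primary")
  # (b): anno + missed true label 3 + fake (both strictly disjoint from anno)
  expect_identical(fb, all_of(c(gt, list(fake))))
  fc <- fuse_masks(anno, pred, "prediction_primary")
  # (c): pred + label 4 missing from the prediction
  expect_identical(fc, all_of(c(gt, list(fake))))
})

test_that("strategy supersets hold for random masks", {
  set.seed(99)
  for (k in 1:30) {
    anno <- random_mask(12, 12, 0.3)
    pred <- random_mask(12, 12, 0.3)
    fa <- fuse_masks(anno, pred, "union")
    fb <- fuse_masks(anno, pred, "annotation_primary")
    fc <- fuse_masks(anno, pred, "prediction_primary")
    expect_true(all(fa >= anno) && all(fa >= pred))
    expect_true(all(fb >= anno))
    expect_true(all(fc >= pred))
    # pixels added by (b)/(c) never intersect the base mask
    expect_false(any((fb & !anno) & anno))
    expect_false(any((fc & !pred) & pred))
    # and every added component of (b) is one of pred's strictly-missing ones
    missing_b <- find_missing_labels(pred, anno)
    expect_identical(which(fb == 1L & anno == 0L),
                     which(missing_b$label_map > 0L))
  }
})

test_that("candidate selection honours the test-set performance gate", {
  dc <- cbind(soma = c(0.95, 0.85, 0.92), vessel = c(0.99, 0.97, 0.96))
  # gate fails when any class's test mean DC is below the gate threshold
  sel <- select_fusion_candidates(dc, c(soma = 0.95, vessel = 0.89))
  expect_false(sel$gate_passed)
  expect_identical(nrow(sel$candidates), 0L)
  # gate passes: training instances below the candidate threshold selected
  sel2 <- select_fusion_candidates(dc, c(soma = 0.95, vessel = 0.93))
  expect_true(sel2$gate_passed)
  expect_identical(sel2$candidates,
                   data.frame(instance = 2L, class = "soma",
                              stringsAsFactors = FALSE))
  # nothing below threshold
  sel3 <- select_fusion_candidates(
    cbind(soma = c(0.95, 0.99), vessel = c(0.97, 0.96)),
    c(soma = 0.95, vessel = 0.93))
  expect_true(sel3$gate_passed)
  expect_identical(nrow(sel3$candidates), 0L)
  expect_error(select_fusion_candidates(dc[, 1, drop = FALSE],
                                        c(soma = 1, vessel = 1)), "class")
})

test_that("apply_fusion replaces only candidate masks and reports pixel counts", {
  anno <- blob(8, 8, 2, 2, 2, 2)
  pred_extra <- blob(8, 8, 6, 5, 3, 4)   # 12 strictly-missing pixels
  insts <- list(make_instance(anno, matrix(0L, 8, 8), "a"),
                make_instance(anno, matrix(0L, 8, 8), "b"))
  preds <- list(list(soma = (anno | pred_extra) * 1.0, vessel = matrix(0, 8, 8)),
                list(soma = anno * 1.0, vessel = matrix(0, 8, 8)))

  # empty candidate set: bit-identical training set
  none <- apply_fusion(insts, preds,
                       data.frame(instance = integer(0), class = character(0)))
  expect_identical(none$train_set, insts)
  expect_identical(nrow(none$report), 0L)

  out <- apply_fusion(insts, preds,
                      data.frame(instance = 1L, class = "soma",
                                 stringsAsFactors = FALSE))
  expect_identical(out$train_set[[1]]$masks$soma,
                   matrix(as.integer(anno | pred_extra), 8, 8))
  expect_identical(out$train_set[[1]]$provenance, "fused")
  expect_identical(out$train_set[[2]], insts[[2]])
  expect_identical(out$report$pixels_added, 12L)
  expect_identical(out$report$n_components_added, 1L)
})

test_that("fusion recovery is exact when predictions equal the ground truth", {
  # delete whole components from the annotation; a perfect predictor plus
  # strategy (b) must restore the mask pixel-exactly.
  set.seed(57)
  for (k in 1:12) {
    ph <- generate_phantom(seed = 500 + k, id = "r")
    for (cl in c("soma", "vessel")) {
      gt <- ph$masks[[cl]]
      comp <- connected_components(gt, 8L)
      if (comp$n_components < 1L) next
      ndel <- sample(seq_len(comp$n_components), 1L)
      drop <- sample(seq_len(comp$n_components), ndel)
      anno <- gt
      anno[comp$label_map %in% drop] <- 0L
      fused <- fuse_masks(anno, gt, "annotation_primary")
      expect_identical(fused, gt)
    }
  }
})
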
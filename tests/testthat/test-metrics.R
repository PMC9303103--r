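test_that("class metrics follow the printed set-cardinality formulas", {
  # |S_a| = |S_b| = 100 with overlap 50 -> IoU 33.3, PA 50, Dice 50
  pred <- matrix(0L, 20, 20); gt <- matrix(0L, 20, 20)
  pred[1:10, 1:10] <- 1L          # 100 predicted
  gt[1:10, 6:15] <- 1L            # 100 true, overlap 50
  m <- class_metrics(pred, gt, 1)
  expect_equal(unname(m["iou"]), 100 * 50 / 150)
  expect_equal(unname(m["pa"]), 50)
  expect_equal(unname(m["dice"]), 50)
  # perfect prediction
  expect_equal(unname(class_metrics(gt, gt, 1)), c(100, 100, 100))
  # disjoint nonempty sets
  gt2 <- matrix(0L, 20, 20); gt2[15:18, 15:18] <- 1L
  expect_equal(unname(class_metrics(pred, gt2, 1)), c(0, 0, 0))
  # absent from both: undefined, flagged as NA
  expect_true(all(is.na(class_metrics(pred, gt, 3))))
  expect_error(class_metrics(pred, matrix(0L, 5, 5), 1), "mismatch")
})

test_that("Dice and IoU satisfy the algebraic identity on random mask pairs", {
  set.seed(61)
  for (rep in 1:50) {
    pred <- matrix(sample(0:3, 144, TRUE), 12)
    gt <- matrix(sample(0:3, 144, TRUE), 12)
    for (k in 1:3) {
      m <- class_metrics(pred, gt, k)
      if (any(is.na(m))) next
      expect_equal(unname(m["dice"]), 2 * m[["iou"]] / (100 + m[["iou"]]) * 100,
                   tolerance = 1e-12)
      expect_lte(m[["iou"]], m[["dice"]])
      expect_lte(m[["dice"]], 100)
    }
    # metrics invariant under a common spatial permutation
    p <- sample(144)
    m1 <- class_metrics(pred, gt, 1)
    m2 <- class_metrics(matrix(pred[p], 12), matrix(gt[p], 12), 1)
    expect_identical(m1, m2)
  }
})

test_that("report construction averages the three vessel classes", {
  pc <- data.frame(iou = c(71.2, 69.7, 64.9), pa = c(83.5, 82.8, 77.8),
                   dice = c(83.2, 82.1, 78.7))
  rep <- metrics_report(pc)
  expect_equal(round(rep$mean[["iou"]], 1), 68.6)
  expect_equal(round(rep$mean[["pa"]], 1), 81.4)
  expect_equal(round(rep$mean[["dice"]], 1), 81.3)
  expect_error(metrics_report(data.frame(iou = c(1, 2, 101), pa = 1:3,
                                         dice = 1:3)), "0, 100")
})

test_that("dataset evaluation: oracle scores 100, aggregations are consistent", {
  man_path <- make_tiny_dataset(2, 1, 3, seed = 23)
  man <- read_manifest(man_path)
  # ground-truth oracle predictor
  masks <- lapply(which(man$split == "test"), function(i) read_mask_png(man$mask[i]))
  imgs <- lapply(which(man$split == "test"), function(i) read_image_png(man$image[i]))
  oracle <- function(image) {
    for (j in seq_along(imgs)) if (identical(imgs[[j]], image)) return(masks[[j]])
    stop("unknown image")
  }
  rep <- evaluate_dataset(oracle, man, "test", "micro")
  expect_equal(unname(rep$mean), c(100, 100, 100))
  expect_equal(rep$n_images, 3L)
  # micro equals a brute-force recount over the concatenated split
  noisy <- function(image) {
    m <- oracle(image)
    m[seq(1, length(m), by = 7)] <- 0L # deterministic corruption
    m
  }
  rep_mi <- evaluate_dataset(noisy, man, "test", "micro")
  big_pred <- do.call(rbind, lapply(imgs, noisy))
  big_gt <- do.call(rbind, masks)
  for (k in 1:3)
    expect_equal(unname(rep_mi$per_class[k, c("iou", "pa", "dice")]),
                 as.data.frame(as.list(class_metrics(big_pred, big_gt, k))),
                 ignore_attr = TRUE)
  # micro and per-image agree exactly on a single-image split
  man1 <- man[man$split != "test" | man$id == man$id[man$split == "test"][1], ]
  r_mi <- evaluate_dataset(noisy, man1, "test", "micro")
  r_pi <- evaluate_dataset(noisy, man1, "test", "per_image")
  expect_equal(r_mi$per_class[, c("iou", "pa", "dice")],
               r_pi$per_class[, c("iou", "pa", "dice")])
  expect_error(evaluate_dataset(noisy, man, "nope"), "empty")
})

test_that("comparisons report mean rows and pairwise deltas", {
  mk <- function(iou, pa, dice)
    metrics_report(data.frame(iou = iou, pa = pa, dice = dice))
  # clinical-scale mean rows: full-image training vs distilled student
  r_base <- mk(c(66.8, 66.8, 66.8), c(79.2, 79.2, 79.2), c(80.1, 80.1, 80.1))
  r_ours <- mk(c(68.6, 68.6, 68.6), c(81.4, 81.4, 81.4), c(81.3, 81.3, 81.3))
  cmp <- compare_report(list(deeplab = r_base, distilled = r_ours))
  expect_equal(round(cmp$deltas$iou, 1), 1.8)
  expect_equal(round(cmp$deltas$pa, 1), 2.2)
  expect_equal(round(cmp$deltas$dice, 1), 1.2)
  # self-comparison: all deltas zero
  cmp0 <- compare_report(list(a = r_ours, b = r_ours))
  expect_equal(unlist(cmp0$deltas[, c("iou", "pa", "dice")]),
               c(iou = 0, pa = 0, dice = 0))
  expect_error(compare_report(list(a = r_ours)), "length")
})
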
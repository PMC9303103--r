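test_that("learning-rate schedule decays exponentially from the initial rate", {
  expect_identical(lr_schedule(5e-4, 0.92, 1), 5e-4) # exponent zero
  expect_equal(lr_schedule(5e-4, 0.92, 2), 0.00046)
  expect_equal(lr_schedule(5e-5, 0.92, 2), 0.000046)
  lrs <- lr_schedule(1e-3, 0.92, 1:50)
  expect_true(all(diff(lrs) < 0))
  expect_identical(lr_schedule(1e-3, 1, 1:10), rep(1e-3, 10))
  expect_error(lr_schedule(1e-3, 0.92, 0), ">= 1")
})

test_that("stage configs carry the two-stage defaults", {
  s1 <- stage_config(1)
  s2 <- stage_config(2)
  expect_equal(s1$lr_init, 5e-4)
  expect_equal(s2$lr_init, 5e-5)
  expect_equal(s1$batch_size, 8L)
  expect_equal(s2$batch_size, 2L)
  expect_true(s1$freeze_backbone)
  expect_false(s2$freeze_backbone)
  expect_equal(s1$max_epochs, 50L)
  expect_equal(s1$patience, 5L)
  expect_error(stage_config(3), "stage")
})

test_that("identity augmentation is a no-op and flips are involutions", {
  s <- generate_sample(phantom_config(image_size = 64, seed = 14), 1)
  set.seed(1)
  out <- augment_sample(s, identity_augment())
  expect_equal(out$image, s$image, tolerance = 1e-12)
  expect_identical(out$mask, s$mask)
  flip_cfg <- augment_config(scale_range = c(1, 1), shift_range = 0,
                             flip_prob = 1, rotate_range = 0,
                             intensity_jitter = list(brightness = 0,
                                                     contrast = 0))
  set.seed(2); once <- augment_sample(s, flip_cfg)
  expect_false(identical(once$mask, s$mask))
  set.seed(3); twice <- augment_sample(once, flip_cfg)
  expect_equal(twice$image, s$image, tolerance = 1e-12)
  expect_identical(twice$mask, s$mask)
})

test_that("augmentation preserves mask integrity and never invents a class", {
  s <- generate_sample(phantom_config(image_size = 64, seed = 15), 2)
  cfg <- augment_config(scale_range = c(0.7, 1.3), shift_range = 0.2,
                        flip_prob = 0.5, rotate_range = 30)
  set.seed(99)
  for (rep in 1:25) {
    out <- augment_sample(s, cfg)
    expect_identical(dim(out$mask), dim(s$mask))
    expect_true(is.integer(out$mask))
    expect_true(all(out$mask %in% unique(as.vector(s$mask))))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("teacher training runs two stages, logs losses and keeps the best checkpoint", {
  man <- make_tiny_dataset(6, 2, 2, seed = 31)
  dir <- withr::local_tempdir()
  ck <- train_teacher(man, tiny_model(seed = 3), short_stages(2, 2, seed = 41),
                      dir, roi_pad = 6)
  expect_true(file.exists(ck))
  net <- load_checkpoint(ck)
  expect_equal(attr(net, "meta")$role, "teacher")
  log <- read_log(ck)
  expect_equal(length(log), 4) # 2 stages x 2 epochs, no early stop
  expect_true(all(sapply(log, function(r) r$train_kd == 0)))
  expect_true(all(sapply(log, function(r)
    abs(r$train_total - (r$train_ce + r$train_dice)) < 1e-9)))
  expect_equal(sapply(log, `[[`, "lr"),
               c(2e-3, 2e-3 * 0.92, 5e-4, 5e-4 * 0.92))
  # deterministic: an identical rerun reproduces the log byte for byte
  dir2 <- withr::local_tempdir()
  ck2 <- train_teacher(man, tiny_model(seed = 3), short_stages(2, 2, seed = 41),
                       dir2, roi_pad = 6)
  expect_identical(readLines(attr(ck, "log")), readLines(attr(ck2, "log")))
  expect_identical(load_checkpoint(ck2)$params, net$params)
})

test_that("distill targets restore teacher logits at the recorded location", {
  man <- make_tiny_dataset(6, 2, 2, seed = 31)
  dir <- withr::local_tempdir()
  ck <- train_teacher(man, tiny_model(seed = 3),
                      short_stages(1, 1, seed = 41), dir, roi_pad = 6)
  teacher <- load_checkpoint(ck)
  # engineered sample whose padded ROI is exactly 64 x 64 (unit scale)
  img <- matrix(runif(128 * 128), 128)
  msk <- matrix(0L, 128, 128)
  msk[45:96, 39:90] <- 1L; msk[50, 50] <- 3L; msk[60, 60] <- 2L # 52 px extent
  sample <- list(image = img, mask = msk, id = "unit")
  tg <- distill_targets(teacher, sample, roi_pad = 6, input_size = 64)
  expect_equal(tg$box$row1 - tg$box$row0, 64L)
  expect_equal(tg$box$col1 - tg$box$col0, 64L)
  expect_equal(sum(tg$valid), 64 * 64)
  crop <- crop_resize(img, tg$box, 64, "bilinear")
  direct <- predict_logits(teacher, crop)
  expect_identical(tg$logits[(tg$box$row0 + 1):tg$box$row1,
                             (tg$box$col0 + 1):tg$box$col1, ], direct)
  # repeated calls are identical (frozen teacher, no stochastic layers)
  tg2 <- distill_targets(teacher, sample, roi_pad = 6, input_size = 64)
  expect_identical(tg, tg2)
  expect_error(distill_targets(teacher, list(image = img,
                                             mask = matrix(0L, 128, 128)),
                               6, 64), "empty mask")
})

test_that("student training logs all three loss components and uses the teacher only when gamma > 0", {
  man <- make_tiny_dataset(6, 2, 2, seed = 31)
  dirt <- withr::local_tempdir()
  tck <- train_teacher(man, tiny_model(seed = 3), short_stages(1, 1, seed = 41),
                       dirt, roi_pad = 6)
  dirs <- withr::local_tempdir()
  sck <- train_student(man, tck, tiny_model(seed = 4),
                       short_stages(2, 2, gamma2 = 3, seed = 51), dirs,
                       roi_pad = 6)
  log <- read_log(sck)
  expect_true(all(c("train_ce", "train_dice", "train_kd") %in% names(log[[1]])))
  stage2 <- Filter(function(r) r$stage == 2, log)
  expect_true(all(sapply(stage2, function(r) r$train_kd > 0)))
  expect_true(all(sapply(Filter(function(r) r$stage == 1, log),
                         function(r) r$train_kd == 0)))
  expect_error(train_student(man, NULL, tiny_model(),
                             short_stages(1, 1, gamma2 = 3), dirs),
               "teacher")
})

test_that("early stopping halts after patience epochs and retains the best weights", {
  man <- make_repeated_sample_dataset(4, seed = 77)
  dir <- withr::local_tempdir()
  # destabilizing learning rate forces validation loss to stall quickly
  stages <- list(stage_config(2, lr_init = 0.2, decay = 1, batch_size = 4,
                              max_epochs = 30, patience = 2,
                              freeze_backbone = FALSE, seed = 6))
  ck <- train_student(man, NULL, tiny_model(seed = 8), stages, dir,
                      augment = identity_augment(), name = "unstable")
  log <- read_log(ck)
  vals <- sapply(log, `[[`, "val_total")
  best_epoch <- which.min(vals)
  expect_lt(length(log), 30) # stopped early
  expect_lte(length(log) - best_epoch, 2) # within patience of the best
  # retained checkpoint reproduces the best validation loss, not the last
  net <- load_checkpoint(ck)
  m <- read_manifest(man)
  s <- cwdistill:::.load_sample(m[m$split == "val", ][1, ])
  l <- combined_loss(s$mask, predict_logits(net, s$image))$total
  expect_equal(l, min(vals), tolerance = 1e-9)
})
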
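#' Learning-rate decay schedule
#'
#' Exponential decay \code{lr_init * decay^(epoch - 1)}: the first epoch
#' runs at the initial rate and each subsequent epoch multiplies it by
#' \code{decay} (0.92 by default).
#'
#' @param lr_init Initial learning rate (> 0).
#' @param decay Multiplicative decay in (0, 1].
#' @param epoch 1-based epoch (or step, under \code{decay_unit = "step"}).
#' @return The decayed learning rate.
#' @export
lr_schedule <- function(lr_init, decay, epoch) {
  stopifnot(lr_init > 0, decay > 0, decay <= 1)
  if (any(epoch < 1)) stop("epoch must be >= 1", call. = FALSE)
  lr_init * decay^(epoch - 1)
}

#' Configure one training stage
#'
#' Training runs in two stages: stage 1 freezes the encoder backbone and
#' trains the context/decoder head at a larger learning rate (5e-4, batch
#' 8); stage 2 unfreezes everything at a smaller rate (5e-5, batch 2).
#' Distillation weights live in \code{weights}; teachers always use
#' \code{gamma = 0}, the distilled student uses \code{gamma = 3, tau = 4}
#' in stage 2 only.
#'
#' @param stage 1 or 2 (selects the defaults below).
#' @param lr_init Initial learning rate; default 5e-4 (stage 1) / 5e-5
#'   (stage 2).
#' @param decay Per-epoch learning-rate decay factor.
#' @param decay_unit Apply the decay per \code{"epoch"} (default) or per
#'   optimizer \code{"step"}.
#' @param batch_size Samples per optimizer step; default 8 / 2 by stage.
#' @param max_epochs Maximum epochs (default 50).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 5).
#' @param weights A [loss_weights()].
#' @param freeze_backbone Freeze the encoder; default TRUE for stage 1.
#' @param seed Stage RNG seed (shuffling and augmentation draws).
#' @return A \code{cw_stage_config}.
#' @export
stage_config <- function(stage, lr_init = NULL, decay = 0.92,
                         decay_unit = c("epoch", "step"), batch_size = NULL,
                         max_epochs = 50L, patience = 5L,
                         weights = loss_weights(), freeze_backbone = NULL,
                         seed = 1L) {
  stopifnot(stage %in% c(1L, 2L))
  decay_unit <- match.arg(decay_unit)
  if (is.null(lr_init)) lr_init <- if (stage == 1) 5e-4 else 5e-5
  if (is.null(batch_size)) batch_size <- if (stage == 1) 8L else 2L
  if (is.null(freeze_backbone)) freeze_backbone <- stage == 1
  stopifnot(lr_init > 0, decay > 0, decay <= 1, batch_size >= 1,
            max_epochs >= 1, patience >= 1,
            inherits(weights, "cw_loss_weights"))
  cfg <- list(stage = as.integer(stage), lr_init = lr_init, decay = decay,
              decay_unit = decay_unit, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), weights = weights,
              freeze_backbone = isTRUE(freeze_backbone),
              seed = as.integer(seed))
  class(cfg) <- "cw_stage_config"
  cfg
}

#' Configure data augmentation
#'
#' Geometric transforms (scaling, displacement, flip, rotation) are applied
#' jointly to image and mask -- the mask is resampled with nearest neighbour
#' so it never invents a class -- while intensity jitter (the grayscale
#' reading of color jittering: brightness/contrast) touches the image only.
#' Zero ranges and \code{flip_prob = 0} give the identity.
#'
#' @param scale_range Length-2 multiplicative scale range.
#' @param shift_range Maximum |shift| as a fraction of the image side.
#' @param flip_prob Probability of a horizontal flip.
#' @param rotate_range Maximum |rotation| in degrees.
#' @param intensity_jitter List with \code{brightness} (additive half-range)
#'   and \code{contrast} (multiplicative half-range).
#' @return A \code{cw_augment_config}.
#' @export
augment_config <- function(scale_range = c(0.9, 1.1), shift_range = 0.05,
                           flip_prob = 0.5, rotate_range = 10,
                           intensity_jitter = list(brightness = 0.1,
                                                   contrast = 0.1)) {
  stopifnot(length(scale_range) == 2, scale_range[1] <= scale_range[2],
            scale_range[1] > 0, shift_range >= 0, flip_prob >= 0,
            flip_prob <= 1, rotate_range >= 0,
            intensity_jitter$brightness >= 0, intensity_jitter$contrast >= 0)
  cfg <- list(scale_range = scale_range, shift_range = shift_range,
              flip_prob = flip_prob, rotate_range = rotate_range,
              intensity_jitter = intensity_jitter)
  class(cfg) <- "cw_augment_config"
  cfg
}

#' Identity augmentation (no-op)
#' @return An [augment_config()] whose transform is the identity.
#' @export
identity_augment <- function() {
  augment_config(scale_range = c(1, 1), shift_range = 0, flip_prob = 0,
                 rotate_range = 0,
                 intensity_jitter = list(brightness = 0, contrast = 0))
}

# Sample one bilinear value per (r, c) source coordinate; out of bounds -> 0.
.sample_bilinear <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
  r <- pmin(pmax(r, 0), H - 1); c <- pmin(pmax(c, 0), W - 1)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c1 + 1)
  i10 <- cbind(r1 + 1, c0 + 1); i11 <- cbind(r1 + 1, c1 + 1)
  v <- (1 - fr) * ((1 - fc) * img[i00] + fc * img[i01]) +
    fr * ((1 - fc) * img[i10] + fc * img[i11])
  v * ok
}

.sample_nearest <- function(mask, r, c) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- floor(r + 0.5); ci <- floor(c + 0.5)
  ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
  ri <- pmin(pmax(ri, 0), H - 1); ci <- pmin(pmax(ci, 0), W - 1)
  v <- mask[cbind(ri + 1, ci + 1)]
  v[!ok] <- 0L
  v
}

#' Apply a random augmentation to a sample
#'
#' Draws flip/rotation/scale/shift/intensity parameters from the current
#' RNG stream, composes them into one affine map about the image centre,
#' and resamples: bilinear for the image (out-of-frame pixels become 0,
#' i.e. anechoic background), nearest for the mask. All parameters are
#' always drawn, so the RNG stream advances identically for every config.
#'
#' @param sample List with \code{image}, \code{mask}, \code{id}.
#' @param config An [augment_config()].
#' @return The augmented sample.
#' @export
augment_sample <- function(sample, config) {
  stopifnot(inherits(config, "cw_augment_config"))
  flip <- stats::runif(1) < config$flip_prob
  ang <- stats::runif(1, -config$rotate_range, config$rotate_range) * pi / 180
  sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
  H <- nrow(sample$image); W <- ncol(sample$image)
  sh_r <- stats::runif(1, -config$shift_range, config$shift_range) * H
  sh_c <- stats::runif(1, -config$shift_range, config$shift_range) * W
  br <- stats::runif(1, -config$intensity_jitter$brightness,
                     config$intensity_jitter$brightness)
  ct <- stats::runif(1, 1 - config$intensity_jitter$contrast,
                     1 + config$intensity_jitter$contrast)

  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  dst_r <- rep(seq_len(H) - 1, times = W) - cy
  dst_c <- rep(seq_len(W) - 1, each = H) - cx
  # invert: dst = R(ang) * S(sc) * F * src + shift
  u <- dst_r - sh_r; v <- dst_c - sh_c
  src_r <- (cos(ang) * u + sin(ang) * v) / sc
  src_c <- (-sin(ang) * u + cos(ang) * v) / sc
  if (flip) src_c <- -src_c
  src_r <- src_r + cy; src_c <- src_c + cx

  img <- matrix(.sample_bilinear(sample$image, src_r, src_c), H, W)
  msk <- matrix(as.integer(.sample_nearest(sample$mask, src_r, src_c)), H, W)
  img <- pmin(pmax(img * ct + br, 0), 1)
  list(image = img, mask = msk, id = sample$id)
}

# ---------------------------------------------------------------- optimizer

.adam_init <- function(params) {
  st <- lapply(params, function(p)
    list(mw = 0 * p$w, vw = 0 * p$w, mb = 0 * p$b, vb = 0 * p$b))
  list(t = 0L, s = st, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adam_step <- function(net, grads, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    if (net$frozen_backbone && net$params[[nm]]$group == "encoder") next
    g <- grads[[nm]]
    s <- opt$s[[nm]]
    s$mw <- b1 * s$mw + (1 - b1) * g$w
    s$vw <- b2 * s$vw + (1 - b2) * g$w^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    net$params[[nm]]$w <- net$params[[nm]]$w -
      lr * (s$mw / corr1) / (sqrt(s$vw / corr2) + opt$eps)
    net$params[[nm]]$b <- net$params[[nm]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + opt$eps)
    opt$s[[nm]] <- s
  }
  list(net = net, opt = opt)
}

# ---------------------------------------------------------------- fit loop

# Shared two-stage fit loop. make_item(sample, training) returns
# list(x, gt, teacher = NULL, support = NULL) or NULL to skip the sample.
# Augmentation (training only) happens inside make_item so that retry
# policies stay identical across roles.
.fit_segmenter <- function(net, train_samples, val_samples, stages,
                           make_item, log_path = NULL) {
  log_lines <- character(0)
  emit <- function(rec) {
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(10))
    log_lines <<- c(log_lines, line)
    if (!is.null(log_path)) cat(line, "\n", sep = "", file = log_path,
                                append = TRUE)
  }
  for (stg in stages) {
    stopifnot(inherits(stg, "cw_stage_config"))
    net <- set_backbone_frozen(net, stg$freeze_backbone)
    opt <- .adam_init(net$params)
    set.seed(stg$seed)
    best_val <- Inf; best_params <- net$params; bad <- 0L
    step <- 0L
    for (epoch in seq_len(stg$max_epochs)) {
      ord <- sample(length(train_samples))
      comp_sum <- c(ce = 0, dice = 0, kd = 0, total = 0); n_used <- 0L
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[i:min(i + stg$batch_size - 1L, length(ord))]
        i <- i + stg$batch_size
        grads <- NULL; nb <- 0L
        for (j in idx) {
          item <- make_item(train_samples[[j]], stg)
          if (is.null(item)) next
          fw <- .segmenter_forward(net, item$x, cache = TRUE)
          wts <- if (is.null(item$teacher) && stg$weights$gamma > 0)
            loss_weights(stg$weights$alpha, stg$weights$beta, 0,
                         stg$weights$tau) else stg$weights
          ls <- combined_loss(item$gt, fw$logits, item$teacher, wts,
                              item$support)
          gl <- .combined_grad(item$gt, fw$logits, item$teacher, wts,
                               item$support)
          gr <- .segmenter_backward(net, fw$cache, gl)
          grads <- if (is.null(grads)) gr else
            mapply(function(a, b) list(w = a$w + b$w, b = a$b + b$b),
                   grads, gr, SIMPLIFY = FALSE)
          nb <- nb + 1L
          comp_sum <- comp_sum + c(ls$ce, ls$dice, ls$kd, ls$total)
          n_used <- n_used + 1L
        }
        if (nb == 0L) next
        grads <- lapply(grads, function(g) list(w = g$w / nb, b = g$b / nb))
        step <- step + 1L
        lr <- if (stg$decay_unit == "epoch")
          lr_schedule(stg$lr_init, stg$decay, epoch)
        else lr_schedule(stg$lr_init, stg$decay, step)
        upd <- .adam_step(net, grads, opt, lr)
        net <- upd$net; opt <- upd$opt
      }
      # validation (no augmentation, deterministic)
      val_total <- 0; nv <- 0L
      for (s in val_samples) {
        item <- make_item(s, stg, training = FALSE)
        if (is.null(item)) next
        lg <- .segmenter_forward(net, item$x, cache = FALSE)
        wts <- if (is.null(item$teacher) && stg$weights$gamma > 0)
          loss_weights(stg$weights$alpha, stg$weights$beta, 0,
                       stg$weights$tau) else stg$weights
        ls <- combined_loss(item$gt, lg, item$teacher, wts, item$support)
        val_total <- val_total + ls$total; nv <- nv + 1L
      }
      val_total <- if (nv > 0) val_total / nv else NA_real_
      lr_epoch <- lr_schedule(stg$lr_init, stg$decay, epoch)
      emit(list(stage = stg$stage, epoch = epoch, lr = lr_epoch,
                train_ce = comp_sum[["ce"]] / max(n_used, 1L),
                train_dice = comp_sum[["dice"]] / max(n_used, 1L),
                train_kd = comp_sum[["kd"]] / max(n_used, 1L),
                train_total = comp_sum[["total"]] / max(n_used, 1L),
                val_total = val_total, n_train_used = n_used))
      if (is.finite(val_total) && val_total < best_val - 1e-12) {
        best_val <- val_total; best_params <- net$params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= stg$patience) break
      }
    }
    net$params <- best_params # best, not last
  }
  list(net = net, log = log_lines)
}

# Augment with up to 5 redraws when the augmented mask loses all
# foreground; falls back to the unaugmented sample. Applied identically in
# every training role so code paths stay byte-equivalent.
.augment_with_retry <- function(sample, aug) {
  for (try in 1:5) {
    out <- augment_sample(sample, aug)
    if (any(out$mask != 0)) return(out)
  }
  sample
}

#' Train the teacher network on ROI crops
#'
#' For every (augmented) training sample, the vessel ROI is extracted from
#' the ground-truth mask, the image is cropped and resized to the square
#' model input (bilinear; mask nearest), and the network is trained with
#' the combined objective at \eqn{\gamma = 0} over the two configured
#' stages. The checkpoint with the best validation loss is kept. Samples
#' with an empty mask are skipped with a warning.
#'
#' @param manifest Manifest path or data frame with train and val splits.
#' @param model_cfg A [model_config()].
#' @param stages List of [stage_config()]s (run in order).
#' @param out_dir Output directory for checkpoint and log.
#' @param augment An [augment_config()] for training samples.
#' @param roi_pad ROI padding per edge in pixels (50 at 512 x 512 scale).
#' @param input_size Square model input size; defaults to the dataset's
#'   image size.
#' @param name Basename for checkpoint/log files.
#' @return Checkpoint path (log path as attribute \code{"log"}).
#' @export
train_teacher <- function(manifest, model_cfg, stages, out_dir,
                          augment = augment_config(), roi_pad = 50L,
                          input_size = NULL, name = "teacher") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  for (stg in stages) stopifnot(stg$weights$gamma == 0)
  ds <- .load_split_samples(manifest)
  if (is.null(input_size)) input_size <- nrow(ds$train[[1]]$image)
  net <- build_segmenter(model_cfg)
  make_item <- function(sample, stg, training = TRUE) {
    if (!any(sample$mask != 0)) {
      warning("sample ", sample$id, " has an empty mask; skipped")
      return(NULL)
    }
    if (training) sample <- .augment_with_retry(sample, augment)
    box <- extract_roi(sample$mask, roi_pad)
    list(x = crop_resize(sample$image, box, input_size, "bilinear"),
         gt = crop_resize(sample$mask, box, input_size, "nearest"))
  }
  .run_training(net, ds, stages, make_item, out_dir, name,
                meta = list(role = "teacher", roi_pad = roi_pad,
                            input_size = input_size))
}

#' Compute full-size distillation targets from a teacher
#'
#' Extracts the ROI from the (augmented) sample's ground-truth mask, crops
#' and resizes the image to the teacher's input, runs the teacher (no
#' gradient), and restores the crop-space logits to full-image coordinates
#' with the recorded box. The validity mask marks the restored ROI.
#'
#' @param teacher A \code{cw_segmenter} or checkpoint path.
#' @param sample List with \code{image} and \code{mask} (mask nonempty).
#' @param roi_pad ROI padding per edge.
#' @param input_size Teacher input size; defaults to the sample size.
#' @return List with \code{logits} (full-size H x W x C), \code{valid}
#'   (H x W 0/1), and \code{box}.
#' @export
distill_targets <- function(teacher, sample, roi_pad = 50L,
                            input_size = NULL) {
  if (is.character(teacher)) teacher <- load_checkpoint(teacher)
  if (!any(sample$mask != 0))
    stop("empty mask: no ROI for distillation", call. = FALSE)
  if (is.null(input_size)) input_size <- nrow(sample$image)
  box <- extract_roi(sample$mask, roi_pad)
  crop <- crop_resize(sample$image, box, input_size, "bilinear")
  lg <- .segmenter_forward(teacher, crop, cache = FALSE)
  res <- restore_logits(lg, box)
  list(logits = res$logits, valid = res$valid, box = box)
}

#' Train the student (or baseline) network on full-size images
#'
#' Stage 1 trains with \eqn{\alpha = \beta = 1, \gamma = 0} and a frozen
#' backbone; stage 2 unfreezes the network and, when the stage's
#' \eqn{\gamma > 0}, adds channel-wise distillation from the frozen
#' teacher's restored logits, computed on-the-fly from each augmented
#' sample so teacher and student see geometrically consistent content. With
#' \eqn{\gamma = 0} in every stage the identical code path trains the no-KD
#' baseline and no teacher is needed.
#'
#' @inheritParams train_teacher
#' @param teacher Teacher checkpoint path or \code{cw_segmenter}; required
#'   iff any stage has \eqn{\gamma > 0}.
#' @param kd_support \code{"roi"} restricts the distillation softmax/sum to
#'   the restored ROI (where the teacher carries information);
#'   \code{"full"} uses all pixels.
#' @param init Optional checkpoint path or \code{cw_segmenter} to warm-start
#'   from instead of a fresh \code{model_cfg} build -- e.g. a shared
#'   stage-1 model branched into distilled and baseline stage-2 arms for a
#'   paired with/without-distillation comparison.
#' @return Checkpoint path (log path as attribute \code{"log"}).
#' @export
train_student <- function(manifest, teacher = NULL, model_cfg, stages,
                          out_dir, augment = augment_config(),
                          roi_pad = 50L, kd_support = c("roi", "full"),
                          name = "student", init = NULL) {
  kd_support <- match.arg(kd_support)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  needs_kd <- any(vapply(stages, function(s) s$weights$gamma > 0, logical(1)))
  if (needs_kd && is.null(teacher))
    stop("a teacher checkpoint is required when gamma > 0", call. = FALSE)
  teacher_net <- NULL
  if (needs_kd)
    teacher_net <- if (is.character(teacher)) load_checkpoint(teacher) else teacher
  ds <- .load_split_samples(manifest)
  input_size <- nrow(ds$train[[1]]$image)
  net <- if (is.null(init)) build_segmenter(model_cfg)
  else if (is.character(init)) load_checkpoint(init) else init
  make_item <- function(sample, stg, training = TRUE) {
    if (training) sample <- .augment_with_retry(sample, augment)
    item <- list(x = sample$image, gt = sample$mask)
    if (stg$weights$gamma > 0 && any(sample$mask != 0)) {
      tg <- distill_targets(teacher_net, sample, roi_pad, input_size)
      item$teacher <- tg$logits
      if (kd_support == "roi") item$support <- tg$valid
    }
    item
  }
  .run_training(net, ds, stages, make_item, out_dir, name,
                meta = list(role = if (needs_kd) "student" else "baseline",
                            roi_pad = roi_pad, kd_support = kd_support))
}

.load_split_samples <- function(manifest) {
  for (sp in c("train", "val"))
    if (!any(manifest$split == sp))
      stop("manifest lacks a '", sp, "' split", call. = FALSE)
  load_rows <- function(sp) {
    rows <- manifest[manifest$split == sp, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i) .load_sample(rows[i, ]))
  }
  list(train = load_rows("train"), val = load_rows("val"))
}

.run_training <- function(net, ds, stages, make_item, out_dir, name, meta) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, paste0(name, "_log.jsonl"))
  if (file.exists(log_path)) file.remove(log_path)
  fit <- .fit_segmenter(net, ds$train, ds$val, stages, make_item, log_path)
  ckpt <- file.path(out_dir, paste0(name, ".rds"))
  meta$stages <- lapply(stages, unclass)
  save_checkpoint(fit$net, ckpt, meta = meta)
  attr(ckpt, "log") <- log_path
  ckpt
}
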
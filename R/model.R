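#' Configure the segmentation network
#'
#' Describes a small DeepLab-style encoder--decoder: a strided convolutional
#' encoder, an optional atrous spatial pyramid context block on the coarsest
#' feature map, and a decoder that fuses a skip connection at half
#' resolution before predicting class logits, which are bilinearly upsampled
#' to the input resolution. Teacher and student use the same architecture.
#'
#' @param in_channels Number of image channels (grayscale ultrasound: 1).
#' @param num_classes Number of classes C including background (default 4:
#'   background, pulmonary artery, aorta, superior vena cava).
#' @param base_width Channel width of the stem; stage widths double per
#'   downsampling stage (capped at 8x).
#' @param depth Number of stride-2 downsampling stages (input height and
#'   width must be divisible by \code{2^depth}).
#' @param use_aspp Use the atrous pyramid context block.
#' @param aspp_rates Dilation rates of the pyramid's 3x3 branches.
#' @param seed Integer seed for the deterministic weight initialization.
#' @return A \code{cw_model_config} list.
#' @export
model_config <- function(in_channels = 1L, num_classes = 4L, base_width = 8L,
                         depth = 2L, use_aspp = TRUE, aspp_rates = c(1L, 2L, 4L),
                         seed = 1L) {
  stopifnot(num_classes >= 2, depth >= 1, base_width >= 2,
            in_channels >= 1, all(aspp_rates >= 1))
  cfg <- list(in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              base_width = as.integer(base_width),
              depth = as.integer(depth),
              use_aspp = isTRUE(use_aspp),
              aspp_rates = as.integer(aspp_rates),
              seed = as.integer(seed))
  class(cfg) <- "cw_model_config"
  cfg
}

# He-normal initialization for a conv parameter block.
.conv_param <- function(cout, cin, k, stride = 1L, dilation = 1L,
                        pad = (k %/% 2L) * dilation, group = "decoder") {
  fan_in <- cin * k * k
  list(w = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = cout),
       b = numeric(cout),
       k = as.integer(k), stride = as.integer(stride),
       dilation = as.integer(dilation), pad = as.integer(pad),
       cin = as.integer(cin), cout = as.integer(cout), group = group)
}

.stage_widths <- function(cfg) cfg$base_width * 2L^pmin(seq_len(cfg$depth), 3L)

#' Build a segmentation network
#'
#' Instantiates the architecture described by a [model_config()] with
#' deterministic He-normal weights drawn from the config's seed. Two builds
#' from the same config are parameter-identical.
#'
#' @param config A [model_config()].
#' @return A \code{cw_segmenter} object (parameters plus config).
#' @export
build_segmenter <- function(config) {
  stopifnot(inherits(config, "cw_model_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  w <- .stage_widths(config)
  w0 <- config$base_width
  wd <- w[config$depth]
  p <- list()
  p$stem <- .conv_param(w0, config$in_channels, 3L, group = "encoder")
  prev <- w0
  for (s in seq_len(config$depth)) {
    p[[sprintf("enc%d_a", s)]] <- .conv_param(w[s], prev, 3L, stride = 2L,
                                              group = "encoder")
    p[[sprintf("enc%d_b", s)]] <- .conv_param(w[s], w[s], 3L, group = "encoder")
    prev <- w[s]
  }
  if (config$use_aspp) {
    wb <- max(4L, wd %/% 2L)
    p$aspp_pw <- .conv_param(wb, wd, 1L)
    for (r in config$aspp_rates)
      p[[sprintf("aspp_r%d", r)]] <- .conv_param(wb, wd, 3L, dilation = r)
    p$aspp_fuse <- .conv_param(wd, wb * (1L + length(config$aspp_rates)), 1L)
  } else {
    p$context <- .conv_param(wd, wd, 3L)
  }
  p$skip_reduce <- .conv_param(w0, w[1], 1L)
  p$decoder <- .conv_param(2L * w0, wd + w0, 3L)
  p$head <- .conv_param(config$num_classes, 2L * w0, 1L)
  net <- list(config = config, params = p, frozen_backbone = FALSE)
  class(net) <- "cw_segmenter"
  net
}

#' Count trainable parameters
#' @param net A \code{cw_segmenter}.
#' @return Integer total number of weights and biases.
#' @export
parameter_count <- function(net) {
  stopifnot(inherits(net, "cw_segmenter"))
  sum(vapply(net$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

.conv_apply <- function(p, x) .conv2d_fw(x, p$w, p$b, p$k, p$stride,
                                         p$dilation, p$pad)

# Forward pass. Returns logits (H x W x C); with cache = TRUE also every
# intermediate needed by .segmenter_backward.
.segmenter_forward <- function(net, x, cache = FALSE) {
  cfg <- net$config
  x <- .as_hwc(x)
  d <- dim(x)
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop("input size ", d[1], "x", d[2], " not divisible by 2^depth = ",
         2^cfg$depth, call. = FALSE)
  if (d[3] != cfg$in_channels)
    stop("expected ", cfg$in_channels, " input channel(s), got ", d[3],
         call. = FALSE)
  p <- net$params
  cc <- if (cache) list(x = x) else NULL
  relu <- function(z, name) {
    m <- z > 0
    if (cache) cc[[paste0("m_", name)]] <<- m
    z * m
  }
  keep <- function(z, name) { if (cache) cc[[name]] <<- z; z }

  f <- relu(.conv_apply(p$stem, x), "stem")
  skip <- NULL
  for (s in seq_len(cfg$depth)) {
    a <- relu(.conv_apply(p[[sprintf("enc%d_a", s)]], keep(f, sprintf("in_enc%d_a", s))),
              sprintf("enc%d_a", s))
    f <- relu(.conv_apply(p[[sprintf("enc%d_b", s)]], keep(a, sprintf("in_enc%d_b", s))),
              sprintf("enc%d_b", s))
    if (s == 1L) skip <- f
  }
  keep(f, "in_context")
  if (cfg$use_aspp) {
    branches <- list(relu(.conv_apply(p$aspp_pw, f), "aspp_pw"))
    for (r in cfg$aspp_rates)
      branches[[length(branches) + 1L]] <-
        relu(.conv_apply(p[[sprintf("aspp_r%d", r)]], f), sprintf("aspp_r%d", r))
    z <- Reduce(.cat_channels, branches)
    ctx <- relu(.conv_apply(p$aspp_fuse, keep(z, "in_aspp_fuse")), "aspp_fuse")
  } else {
    ctx <- relu(.conv_apply(p$context, f), "context")
  }
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  up <- .resize_bilinear(ctx, h2, w2)
  if (cache) { cc$ctx_h <- dim(ctx)[1]; cc$ctx_w <- dim(ctx)[2] }
  sk <- relu(.conv_apply(p$skip_reduce, keep(skip, "in_skip_reduce")), "skip_reduce")
  dec_in <- keep(.cat_channels(up, sk), "in_decoder")
  dec <- relu(.conv_apply(p$decoder, dec_in), "decoder")
  half_logits <- .conv_apply(p$head, keep(dec, "in_head"))
  logits <- .resize_bilinear(half_logits, d[1], d[2])
  if (cache) list(logits = logits, cache = cc) else logits
}

# Backward pass: gradient of a scalar loss with respect to every parameter,
# given the gradient g_logits at the full-resolution output.
.segmenter_backward <- function(net, cache, g_logits) {
  cfg <- net$config
  p <- net$params
  g <- list()
  d <- dim(cache$x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L

  conv_bw <- function(name, x_in, gy) {
    r <- .conv2d_bw(x_in, p[[name]]$w, gy, p[[name]]$k, p[[name]]$stride,
                    p[[name]]$dilation, p[[name]]$pad)
    g[[name]] <<- list(w = r$gw, b = as.numeric(r$gb))
    r$gx
  }

  gh <- .resize_bilinear_bw(g_logits, h2, w2)
  g_dec <- conv_bw("head", cache$in_head, gh)
  g_dec <- g_dec * cache$m_decoder
  g_cat <- conv_bw("decoder", cache$in_decoder, g_dec)
  wd <- dim(g_cat)[3] - p$skip_reduce$cout
  g_up <- g_cat[, , seq_len(wd), drop = FALSE]
  g_sk <- g_cat[, , wd + seq_len(p$skip_reduce$cout), drop = FALSE]
  g_sk <- g_sk * cache$m_skip_reduce
  g_skip <- conv_bw("skip_reduce", cache$in_skip_reduce, g_sk)
  g_ctx <- .resize_bilinear_bw(g_up, cache$ctx_h, cache$ctx_w)

  if (cfg$use_aspp) {
    g_ctx <- g_ctx * cache$m_aspp_fuse
    g_z <- conv_bw("aspp_fuse", cache$in_aspp_fuse, g_ctx)
    wb <- p$aspp_pw$cout
    g_f <- 0
    nm <- c("aspp_pw", sprintf("aspp_r%d", cfg$aspp_rates))
    for (j in seq_along(nm)) {
      gz <- g_z[, , (j - 1L) * wb + seq_len(wb), drop = FALSE]
      gz <- gz * cache[[paste0("m_", nm[j])]]
      g_f <- g_f + conv_bw(nm[j], cache$in_context, gz)
    }
  } else {
    g_ctx <- g_ctx * cache$m_context
    g_f <- conv_bw("context", cache$in_context, g_ctx)
  }

  for (s in rev(seq_len(cfg$depth))) {
    if (s == 1L) g_f <- g_f + g_skip # skip branch taps the stage-1 output
    g_f <- g_f * cache[[sprintf("m_enc%d_b", s)]]
    g_f <- conv_bw(sprintf("enc%d_b", s), cache[[sprintf("in_enc%d_b", s)]], g_f)
    g_f <- g_f * cache[[sprintf("m_enc%d_a", s)]]
    g_f <- conv_bw(sprintf("enc%d_a", s), cache[[sprintf("in_enc%d_a", s)]], g_f)
  }
  g_f <- g_f * cache$m_stem
  conv_bw("stem", cache$x, g_f)
  g
}

#' Freeze or unfreeze the encoder ("backbone")
#'
#' When frozen, the stem and all encoder stages are excluded from optimizer
#' updates; the context block, decoder, skip reduction and prediction head
#' remain trainable. Returns the modified network (R copy semantics).
#'
#' @param net A \code{cw_segmenter}.
#' @param frozen Logical.
#' @return The network with the freeze flag set.
#' @export
set_backbone_frozen <- function(net, frozen) {
  stopifnot(inherits(net, "cw_segmenter"), is.logical(frozen), length(frozen) == 1)
  net$frozen_backbone <- isTRUE(frozen)
  net
}

#' Predict class logits for one image
#' @param net A \code{cw_segmenter} or checkpoint path.
#' @param image H x W matrix (or H x W x in_channels array) of intensities.
#' @return H x W x num_classes array of logits.
#' @export
predict_logits <- function(net, image) {
  if (is.character(net)) net <- load_checkpoint(net)
  .segmenter_forward(net, image, cache = FALSE)
}

#' Predict a class mask for one image
#' @inheritParams predict_logits
#' @return H x W integer matrix of class ids (0 = background).
#' @export
predict_mask <- function(net, image) {
  lg <- predict_logits(net, image)
  d <- dim(lg)
  m <- matrix(max.col(matrix(lg, d[1] * d[2], d[3]), ties.method = "first") - 1L,
              d[1], d[2])
  m
}

#' Save a self-describing checkpoint
#'
#' The checkpoint stores parameters, the model config, and free-form stage
#' metadata, so it can be reloaded without the original experiment config.
#'
#' @param net A \code{cw_segmenter}.
#' @param path Destination file.
#' @param meta Optional list of training-stage metadata.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(net, path, meta = list()) {
  stopifnot(inherits(net, "cw_segmenter"))
  obj <- list(params = net$params, config = net$config, meta = meta,
              package = "cwdistill",
              version = as.character(utils::packageVersion("cwdistill")))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return A \code{cw_segmenter} with a \code{meta} attribute.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (is.null(obj$params) || is.null(obj$config))
    stop("not a cwdistill checkpoint: ", path, call. = FALSE)
  net <- list(config = obj$config, params = obj$params, frozen_backbone = FALSE)
  class(net) <- "cw_segmenter"
  attr(net, "meta") <- obj$meta
  net
}

# -- RNG bookkeeping: seeded helpers must not disturb the caller's stream --
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
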
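#' Configure the synthetic three-vessel ultrasound phantom
#'
#' The phantom emulates the statistical structure of a fetal-heart
#' three-vessel view: a dark speckle-noise field containing three
#' bright-rimmed, roughly collinear vessel cross-sections of unequal size
#' (pulmonary artery = class 1, aorta = class 2, superior vena cava =
#' class 3, strictly the smallest), with blurred boundaries and low
#' contrast. Vessel geometry defaults are expressed at a 512 x 512 image
#' and scaled proportionally for other sizes, so the foreground occupies
#' only a small fraction of the image at every scale.
#'
#' @param image_size Side length in pixels (square images, default 512).
#' @param vessel_specs List of exactly 3 specs, each
#'   \code{list(class, axes = c(a, b), contrast)}: class id in 1..3, ellipse
#'   semi-axes in pixels, interior contrast in (0, 1]. Default geometry makes
#'   class 3 strictly the smallest by area.
#' @param speckle_scale Standard deviation of the unit-mean multiplicative
#'   speckle field (0 disables noise).
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables blur).
#' @param placement_jitter Per-vessel center jitter in pixels.
#' @param seed Integer seed; with a sample index it fully determines each
#'   generated image.
#' @return A \code{cw_phantom_config}.
#' @export
phantom_config <- function(image_size = 512L,
                           vessel_specs = NULL,
                           speckle_scale = 0.35,
                           blur_sigma = NULL,
                           placement_jitter = NULL,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(image_size >= 16, speckle_scale >= 0)
  sc <- image_size / 512
  if (is.null(vessel_specs)) {
    vessel_specs <- list(
      list(class = 1L, axes = c(42, 36) * sc, contrast = 0.55), # PA
      list(class = 2L, axes = c(38, 33) * sc, contrast = 0.50), # AO
      list(class = 3L, axes = c(20, 17) * sc, contrast = 0.45)  # SVC
    )
  }
  if (is.null(blur_sigma)) blur_sigma <- max(0.8, 1.5 * sc)
  if (is.null(placement_jitter)) placement_jitter <- max(1, 8 * sc)
  if (length(vessel_specs) != 3)
    stop("exactly 3 vessel specs required", call. = FALSE)
  ids <- vapply(vessel_specs, function(v) as.integer(v$class), integer(1))
  if (!setequal(ids, 1:3) || anyDuplicated(ids))
    stop("vessel spec class ids must be {1,2,3}, each once", call. = FALSE)
  areas <- vapply(vessel_specs, function(v) pi * prod(v$axes), numeric(1))
  a3 <- areas[ids == 3L]
  if (!(a3 < areas[ids == 1L] && a3 < areas[ids == 2L]))
    stop("class 3 (SVC) must be strictly smallest by area", call. = FALSE)
  ctr <- vapply(vessel_specs, function(v) v$contrast, numeric(1))
  if (any(ctr <= 0 | ctr > 1))
    stop("vessel contrast must lie in (0, 1]", call. = FALSE)
  cfg <- list(image_size = image_size, vessel_specs = vessel_specs,
              speckle_scale = speckle_scale, blur_sigma = blur_sigma,
              placement_jitter = placement_jitter, seed = as.integer(seed))
  class(cfg) <- "cw_phantom_config"
  cfg
}

.phantom_bg <- 0.18

# Deterministic per-sample stream seed (kept well inside 32-bit range).
.derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

# Place three roughly collinear ellipses; returns list of centers/axes/phi
# or NULL when the draw collides with a border or another vessel.
.place_vessels <- function(cfg) {
  S <- cfg$image_size
  specs <- cfg$vessel_specs[order(vapply(cfg$vessel_specs,
                                         function(v) v$class, numeric(1)))]
  phi <- stats::runif(1, -pi / 12, pi / 12) # line angle around horizontal
  a <- vapply(specs, function(v) v$axes[1], numeric(1))
  gap <- max(4, 10 * S / 512)
  pos <- c(0, a[1] + gap + a[2], a[1] + 2 * gap + 2 * a[2] + a[3])
  pos <- pos - mean(pos)
  ctr <- S / 2
  out <- vector("list", 3)
  for (j in 1:3) {
    jx <- stats::runif(1, -cfg$placement_jitter, cfg$placement_jitter)
    jy <- stats::runif(1, -cfg$placement_jitter, cfg$placement_jitter)
    cy <- ctr + pos[j] * sin(phi) + jy
    cx <- ctr + pos[j] * cos(phi) + jx
    r <- max(specs[[j]]$axes)
    if (cy - r < 2 || cy + r > S - 1 || cx - r < 2 || cx + r > S - 1)
      return(NULL)
    out[[j]] <- list(class = specs[[j]]$class, cy = cy, cx = cx,
                     axes = specs[[j]]$axes, contrast = specs[[j]]$contrast,
                     phi = phi)
  }
  for (j in 1:2) for (k in (j + 1):3) {
    dd <- sqrt((out[[j]]$cy - out[[k]]$cy)^2 + (out[[j]]$cx - out[[k]]$cx)^2)
    if (dd < max(out[[j]]$axes) + max(out[[k]]$axes) + 2) return(NULL)
  }
  out
}

#' Generate one phantom image/mask pair
#'
#' Renders three bright-rimmed elliptical vessel cross-sections on a dark
#' background, multiplies by unit-mean gamma speckle, applies Gaussian
#' blur, and clips to [0, 1]. The result is a deterministic function of
#' \code{(config$seed, index)}. With \code{speckle_scale = 0} and
#' \code{blur_sigma = 0} the image is piecewise constant and its level sets
#' coincide exactly with the mask regions.
#'
#' @param config A [phantom_config()].
#' @param index Positive sample index.
#' @return List with \code{image} (H x W in [0,1]), \code{mask}
#'   (H x W integer in 0..3) and \code{id}.
#' @export
generate_sample <- function(config, index) {
  stopifnot(inherits(config, "cw_phantom_config"), index >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(config$seed, index))
  S <- config$image_size
  vessels <- NULL
  for (try in 1:50) {
    vessels <- .place_vessels(config)
    if (!is.null(vessels)) break
  }
  if (is.null(vessels))
    stop("could not place non-overlapping vessels inside a ", S, "x", S,
         " image after 50 attempts (jitter ", config$placement_jitter,
         "); reduce vessel sizes or jitter", call. = FALSE)

  yy <- matrix(seq_len(S) - 0.5, S, S)
  xx <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
  img <- matrix(.phantom_bg, S, S)
  mask <- matrix(0L, S, S)
  rim_t <- max(1.5, 4 * S / 512)
  for (v in vessels) {
    dy <- yy - v$cy; dx <- xx - v$cx
    u <- (dx * cos(v$phi) + dy * sin(v$phi)) / v$axes[1]
    w <- (-dx * sin(v$phi) + dy * cos(v$phi)) / v$axes[2]
    inside <- u^2 + w^2 <= 1
    ui <- (dx * cos(v$phi) + dy * sin(v$phi)) / max(v$axes[1] - rim_t, 1)
    wi <- (-dx * sin(v$phi) + dy * cos(v$phi)) / max(v$axes[2] - rim_t, 1)
    lumen <- ui^2 + wi^2 <= 1
    rim <- inside & !lumen
    mask[inside] <- v$class
    img[lumen] <- .phantom_bg + 0.25 * v$contrast
    img[rim] <- min(1, .phantom_bg + 0.25 * v$contrast + 0.45)
  }
  if (config$speckle_scale > 0) {
    ss <- config$speckle_scale
    speckle <- matrix(stats::rgamma(S * S, shape = 1 / ss^2, scale = ss^2), S, S)
    img <- img * speckle
  }
  if (config$blur_sigma > 0) img <- .gaussian_blur(img, config$blur_sigma)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, id = sprintf("ph%06d", as.integer(index)))
}

.write_gray_png <- function(m, path) {
  png::writePNG(m, path)
}

#' Read an image or mask PNG written by [generate_dataset()]
#'
#' Masks are stored as 8-bit grayscale PNG whose pixel value is the class
#' id, so reading multiplies the decoded [0,1] intensities back by 255.
#'
#' @param path PNG file path.
#' @return \code{read_image_png}: H x W matrix in [0,1];
#'   \code{read_mask_png}: H x W integer matrix of class ids.
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Generate a phantom dataset on disk
#'
#' Writes grayscale image PNGs, class-id mask PNGs and a CSV manifest with
#' header \code{id,split,image,mask} (paths relative to \code{out_dir}).
#' Splits are disjoint and assigned in order train, val, test. Regenerating
#' with the same config yields byte-identical files.
#'
#' @param config A [phantom_config()].
#' @param n_train,n_val,n_test Positive split sizes (the clinical-scale
#'   call is 1040/130/130).
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest CSV; the manifest data frame as the
#'   \code{"manifest"} attribute.
#' @export
generate_dataset <- function(config, n_train, n_val, n_test, out_dir) {
  stopifnot(inherits(config, "cw_phantom_config"),
            n_train >= 1, n_val >= 1, n_test >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_val + n_test
  split <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(config, i)
    img_rel <- file.path("images", paste0(s$id, ".png"))
    msk_rel <- file.path("masks", paste0(s$id, ".png"))
    .write_gray_png(s$image, file.path(out_dir, img_rel))
    .write_gray_png(s$mask / 255, file.path(out_dir, msk_rel))
    rows[[i]] <- data.frame(id = s$id, split = split[i], image = img_rel,
                            mask = msk_rel, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.table(manifest, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  attr(path, "manifest") <- manifest
  path
}

#' Read a dataset manifest
#' @param path Manifest CSV written by [generate_dataset()].
#' @return Data frame with absolute \code{image}/\code{mask} paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "split", "image", "mask")
  if (!all(need %in% names(m)))
    stop("manifest must have columns id,split,image,mask", call. = FALSE)
  base <- dirname(normalizePath(path))
  m$image <- file.path(base, m$image)
  m$mask <- file.path(base, m$mask)
  m
}

# Load one manifest row into an in-memory sample.
.load_sample <- function(row) {
  if (!file.exists(row$image) || !file.exists(row$mask))
    stop("missing files for sample ", row$id, call. = FALSE)
  list(image = read_image_png(row$image), mask = read_mask_png(row$mask),
       id = row$id)
}
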
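#' Rectangular region-of-interest box
#'
#' Coordinates are 0-based and half-open: the box covers rows
#' \code{[row0, row1)} and columns \code{[col0, col1)} of a
#' \code{full_height} x \code{full_width} image. The box records the source
#' image size so that crop-space predictions can be restored to the exact
#' full-image location.
#'
#' @param row0,col0,row1,col1 Pixel indices (0-based, half-open).
#' @param full_height,full_width Source image size in pixels.
#' @return A \code{cw_roi_box}.
#' @export
roi_box <- function(row0, col0, row1, col1, full_height, full_width) {
  b <- list(row0 = as.integer(row0), col0 = as.integer(col0),
            row1 = as.integer(row1), col1 = as.integer(col1),
            full_height = as.integer(full_height),
            full_width = as.integer(full_width))
  if (!(b$row0 >= 0 && b$row0 < b$row1 && b$row1 <= b$full_height))
    stop("invalid row extent [", b$row0, ",", b$row1, ") for height ",
         b$full_height, call. = FALSE)
  if (!(b$col0 >= 0 && b$col0 < b$col1 && b$col1 <= b$full_width))
    stop("invalid col extent [", b$col0, ",", b$col1, ") for width ",
         b$full_width, call. = FALSE)
  class(b) <- "cw_roi_box"
  b
}

#' @export
format.cw_roi_box <- function(x, ...) {
  sprintf("RoiBox[%d:%d) x [%d:%d) in %dx%d", x$row0, x$row1, x$col0, x$col1,
          x$full_height, x$full_width)
}

#' @export
print.cw_roi_box <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Serialize / deserialize an ROI box as JSON
#' @param box A [roi_box()].
#' @return \code{roi_box_to_json}: a JSON string;
#'   \code{roi_box_from_json}: the reconstructed box (exact round-trip).
#' @export
roi_box_to_json <- function(box) {
  stopifnot(inherits(box, "cw_roi_box"))
  jsonlite::toJSON(unclass(box), auto_unbox = TRUE)
}

#' @rdname roi_box_to_json
#' @param json JSON string produced by \code{roi_box_to_json}.
#' @export
roi_box_from_json <- function(json) {
  v <- jsonlite::fromJSON(json)
  roi_box(v$row0, v$col0, v$row1, v$col1, v$full_height, v$full_width)
}

#' Extract the vessel region of interest from a label mask
#'
#' Takes the tight bounding box of all nonzero (vessel) pixels, pads it by a
#' fixed margin on each of the four edges, and clips the result to the image
#' bounds. Depends only on the nonzero support of the mask, not on which
#' class each pixel carries.
#'
#' @param mask H x W integer class mask with at least one nonzero pixel.
#' @param pad Padding per edge in pixels (default 50, matching a 512 x 512
#'   full-size image).
#' @return A [roi_box()].
#' @export
extract_roi <- function(mask, pad = 50L) {
  stopifnot(is.matrix(mask), pad >= 0)
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0)
    stop("mask has no foreground pixels; no ROI definable", call. = FALSE)
  pad <- as.integer(pad)
  roi_box(max(0L, min(fg[, 1]) - 1L - pad),
          max(0L, min(fg[, 2]) - 1L - pad),
          min(nrow(mask), max(fg[, 1]) + pad),
          min(ncol(mask), max(fg[, 2]) + pad),
          nrow(mask), ncol(mask))
}

#' Crop a box from an image, mask or logits map and resize to a square
#'
#' The crop is resized to \code{out_size} x \code{out_size} with independent
#' axis scaling (aspect ratio is not preserved). Use \code{"bilinear"} for
#' intensity images and logits, \code{"nearest"} for integer masks (nearest
#' resampling never invents values).
#'
#' @param x H x W matrix or H x W x C array.
#' @param box A [roi_box()] whose full size matches \code{x}.
#' @param out_size Output side length in pixels.
#' @param interp \code{"bilinear"} or \code{"nearest"}.
#' @return \code{out_size} x \code{out_size} (x C) array.
#' @export
crop_resize <- function(x, box, out_size = 512L,
                        interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(box, "cw_roi_box"), out_size >= 1)
  d <- dim(x)
  if (d[1] != box$full_height || d[2] != box$full_width)
    stop("array size ", d[1], "x", d[2], " does not match box full size ",
         box$full_height, "x", box$full_width, call. = FALSE)
  rows <- (box$row0 + 1L):box$row1
  cols <- (box$col0 + 1L):box$col1
  crop <- if (length(d) == 3) x[rows, cols, , drop = FALSE] else x[rows, cols, drop = FALSE]
  if (interp == "bilinear") .resize_bilinear(crop, out_size, out_size)
  else .resize_nearest(crop, out_size, out_size)
}

#' Restore crop-space logits into full-image coordinates
#'
#' Inverts [crop_resize()]: resizes a square crop-space logits map back to
#' the box's height and width (bilinear, per channel) and places it at the
#' recorded location in a full-size map. Pixels outside the box carry
#' \code{fill} and are marked invalid. When the box's height and width both
#' equal the crop size (unit scale) the ROI content is recovered exactly.
#'
#' @param crop_logits S x S x C array (square crop-space logits).
#' @param box The [roi_box()] recorded at crop time.
#' @param fill Value assigned outside the box.
#' @return List with \code{logits} (full_height x full_width x C) and
#'   \code{valid} (full_height x full_width 0/1 matrix, 1 inside the box).
#' @export
restore_logits <- function(crop_logits, box, fill = 0) {
  stopifnot(inherits(box, "cw_roi_box"))
  x <- .as_hwc(crop_logits)
  d <- dim(x)
  if (d[1] != d[2]) stop("crop logits must be square", call. = FALSE)
  bh <- box$row1 - box$row0
  bw <- box$col1 - box$col0
  back <- .resize_bilinear(x, bh, bw)
  back <- .as_hwc(back)
  full <- array(fill, dim = c(box$full_height, box$full_width, d[3]))
  rows <- (box$row0 + 1L):box$row1
  cols <- (box$col0 + 1L):box$col1
  full[rows, cols, ] <- back
  valid <- matrix(0L, box$full_height, box$full_width)
  valid[rows, cols] <- 1L
  list(logits = full, valid = valid)
}
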
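#' Per-class overlap metrics for one mask pair
#'
#' With \eqn{S_a} the pixels predicted as \code{class_id} and \eqn{S_b} the
#' ground-truth pixels of that class:
#' \deqn{IoU = |S_a \cap S_b| / |S_a \cup S_b| \times 100}
#' \deqn{PA = |S_a \cap S_b| / |S_a| \times 100}
#' \deqn{Dice = 2 |S_a \cap S_b| / (|S_a| + |S_b|) \times 100}
#' PA is implemented verbatim as intersection over the \emph{predicted}
#' area. A metric whose denominator is zero is returned as \code{NA}
#' (undefined), never silently 0 or 100.
#'
#' @param pred_mask,gt_mask Integer class masks of identical shape.
#' @param class_id Class to evaluate.
#' @return Named numeric \code{c(iou, pa, dice)} in percent, with
#'   \code{NA} for undefined entries.
#' @export
class_metrics <- function(pred_mask, gt_mask, class_id) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("mask shape mismatch", call. = FALSE)
  a <- pred_mask == class_id
  b <- gt_mask == class_id
  .metrics_from_counts(sum(a & b), sum(a | b), sum(a), sum(b))
}

.metrics_from_counts <- function(inter, union, na, nb) {
  c(iou = if (union > 0) 100 * inter / union else NA_real_,
    pa = if (na > 0) 100 * inter / na else NA_real_,
    dice = if (na + nb > 0) 100 * 2 * inter / (na + nb) else NA_real_)
}

.class_names <- c("Pulmonary artery (PA)", "Aorta (AO)",
                  "Superior vena cava (SVC)")

#' Assemble a metrics report from per-class values
#'
#' Builds the Table-style report (classes 1..3 as rows, IoU/PA/Dice as
#' columns) and appends the mean row: the arithmetic mean over the three
#' vessel classes of each metric. Background never enters the mean.
#'
#' @param per_class 3 x 3 numeric matrix or data frame with columns
#'   \code{iou}, \code{pa}, \code{dice} and one row per class 1..3 (in
#'   percent).
#' @param n_images Number of evaluated images (metadata).
#' @param aggregation \code{"micro"} or \code{"per_image"} (metadata).
#' @return A \code{cw_metrics_report}.
#' @export
metrics_report <- function(per_class, n_images = NA_integer_,
                           aggregation = c("micro", "per_image")) {
  aggregation <- match.arg(aggregation)
  pc <- as.data.frame(per_class)
  stopifnot(nrow(pc) == 3, all(c("iou", "pa", "dice") %in% names(pc)))
  pc <- pc[, c("iou", "pa", "dice")]
  ok <- unlist(pc[!is.na(pc)])
  if (length(ok) && (any(ok < 0) || any(ok > 100)))
    stop("metrics must lie in [0, 100]", call. = FALSE)
  rep <- list(per_class = data.frame(class = 1:3, name = .class_names, pc),
              mean = colMeans(pc),
              n_images = as.integer(n_images), aggregation = aggregation)
  class(rep) <- "cw_metrics_report"
  rep
}

#' @export
print.cw_metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "  n/a", sprintf("%5.1f", v))
  cat(sprintf("%-26s %8s %8s %8s\n", "", "IoU (%)", "PA (%)", "Dice (%)"))
  for (i in 1:3)
    cat(sprintf("%-26s %8s %8s %8s\n", x$per_class$name[i],
                fmt(x$per_class$iou[i]), fmt(x$per_class$pa[i]),
                fmt(x$per_class$dice[i])))
  cat(sprintf("%-26s %8s %8s %8s\n", "Mean", fmt(x$mean["iou"]),
              fmt(x$mean["pa"]), fmt(x$mean["dice"])))
  cat(sprintf("(%s aggregation over %s images)\n", x$aggregation,
              ifelse(is.na(x$n_images), "?", x$n_images)))
  invisible(x)
}

#' Evaluate a segmentation model over a dataset split
#'
#' Runs the model on every image of the split and scores predicted against
#' ground-truth masks for vessel classes 1..3. \code{"micro"} aggregation
#' accumulates intersection/union/area pixel counts over all images and
#' applies the metric formulas once per class; \code{"per_image"} averages
#' the defined per-image metrics (an image where a class is absent from
#' both masks is excluded from that class's average).
#'
#' @param model A \code{cw_segmenter}, a checkpoint path, or a function
#'   \code{function(image) -> integer mask} (e.g. a ground-truth oracle).
#' @param manifest Manifest path or data frame from [read_manifest()].
#' @param split Which split to evaluate.
#' @param aggregation \code{"micro"} (default) or \code{"per_image"}.
#' @return A \code{cw_metrics_report}.
#' @export
evaluate_dataset <- function(model, manifest, split = "test",
                             aggregation = c("micro", "per_image")) {
  aggregation <- match.arg(aggregation)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0) stop("split '", split, "' is empty", call. = FALSE)
  missing <- rows$id[!file.exists(rows$image) | !file.exists(rows$mask)]
  if (length(missing))
    stop("missing files for ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  predict_fun <- if (is.function(model)) model else {
    net <- if (is.character(model)) load_checkpoint(model) else model
    function(image) predict_mask(net, image)
  }
  acc <- array(0, dim = c(3, 4)) # class x (inter, union, |Sa|, |Sb|)
  per_img <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    s <- .load_sample(rows[i, ])
    pred <- predict_fun(s$image)
    m <- matrix(NA_real_, 3, 3)
    for (k in 1:3) {
      a <- pred == k; b <- s$mask == k
      cnt <- c(sum(a & b), sum(a | b), sum(a), sum(b))
      acc[k, ] <- acc[k, ] + cnt
      m[k, ] <- .metrics_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    }
    per_img[[i]] <- m
  }
  if (aggregation == "micro") {
    pc <- t(vapply(1:3, function(k)
      .metrics_from_counts(acc[k, 1], acc[k, 2], acc[k, 3], acc[k, 4]),
      numeric(3)))
  } else {
    stack <- simplify2array(per_img) # 3 x 3 x n
    pc <- apply(stack, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
  }
  colnames(pc) <- c("iou", "pa", "dice")
  metrics_report(pc, n_images = nrow(rows), aggregation = aggregation)
}

#' Compare metrics reports across methods
#'
#' Emits a comparison matrix (method x mean metric) plus pairwise deltas
#' (\code{later - earlier}, in percentage points) for each metric.
#'
#' @param reports Named list of at least two \code{cw_metrics_report}s.
#' @return A \code{cw_metrics_comparison}: list with \code{table} and
#'   \code{deltas} data frames.
#' @export
compare_report <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2,
            !is.null(names(reports)), all(nzchar(names(reports))))
  tab <- do.call(rbind, lapply(reports, function(r) {
    stopifnot(inherits(r, "cw_metrics_report"))
    as.data.frame(as.list(r$mean))
  }))
  tab <- cbind(method = names(reports), tab)
  rownames(tab) <- NULL
  pairs <- utils::combn(seq_along(reports), 2)
  deltas <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- reports[[i2]]$mean - reports[[i1]]$mean
    data.frame(from = names(reports)[i1], to = names(reports)[i2],
               iou = d[["iou"]], pa = d[["pa"]], dice = d[["dice"]])
  }))
  out <- list(table = tab, deltas = deltas)
  class(out) <- "cw_metrics_comparison"
  out
}

#' @export
print.cw_metrics_comparison <- function(x, ...) {
  cat(sprintf("%-16s %8s %8s %8s\n", "Method", "IoU (%)", "PA (%)", "Dice (%)"))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("%-16s %8.1f %8.1f %8.1f\n", x$table$method[i],
                x$table$iou[i], x$table$pa[i], x$table$dice[i]))
  cat("Deltas (to - from):\n")
  for (i in seq_len(nrow(x$deltas)))
    cat(sprintf("  %s -> %s: IoU %+.1f, PA %+.1f, Dice %+.1f\n",
                x$deltas$from[i], x$deltas$to[i], x$deltas$iou[i],
                x$deltas$pa[i], x$deltas$dice[i]))
  invisible(x)
}
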
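# Internal array numerics: separable bilinear/nearest resampling and
# Gaussian blur, all expressed as small interpolation matrices so that the
# backward pass of a resize is exactly the transpose of the forward pass.

.interp_cache <- new.env(parent = emptyenv())

# Row-interpolation matrix A (n_out x n_in): out = A %*% in.
# Pixel-centre convention: out index i samples source coordinate
# (i + 0.5) * n_in / n_out - 0.5, clamped to the valid range, so that
# n_in == n_out yields the exact identity matrix.
.bilinear_matrix <- function(n_in, n_out) {
  key <- sprintf("b_%d_%d", n_in, n_out)
  hit <- .interp_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (n_in == n_out) {
    A <- diag(n_out)
  } else {
    i <- seq_len(n_out) - 1
    src <- (i + 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    i0 <- floor(src)
    w1 <- src - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), i0 + 1)] <- 1 - w1
    A[cbind(seq_len(n_out), i1 + 1)] <- A[cbind(seq_len(n_out), i1 + 1)] + w1
  }
  .interp_cache[[key]] <- A
  A
}

# Nearest-neighbour source index (1-based) for each of n_out positions.
.nearest_index <- function(n_in, n_out) {
  i <- seq_len(n_out) - 1
  src <- (i + 0.5) * n_in / n_out - 0.5
  idx <- floor(src + 0.5)
  pmin(pmax(idx, 0), n_in - 1) + 1L
}

.as_hwc <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# Bilinear resize of an H x W (xC) array to h_out x w_out, per channel.
.resize_bilinear <- function(x, h_out, w_out) {
  was_mat <- is.matrix(x)
  x <- .as_hwc(x)
  d <- dim(x)
  if (d[1] == h_out && d[2] == w_out) {
    return(if (was_mat) x[, , 1] else x)
  }
  Ar <- .bilinear_matrix(d[1], h_out)
  Ac <- .bilinear_matrix(d[2], w_out)
  out <- array(0, dim = c(h_out, w_out, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Ar %*% x[, , c] %*% t(Ac)
  if (was_mat) out[, , 1] else out
}

# Adjoint of .resize_bilinear: pushes a gradient on the h_out x w_out grid
# back to the h_in x w_in grid.
.resize_bilinear_bw <- function(g, h_in, w_in) {
  was_mat <- is.matrix(g)
  g <- .as_hwc(g)
  d <- dim(g)
  if (d[1] == h_in && d[2] == w_in) {
    return(if (was_mat) g[, , 1] else g)
  }
  Ar <- .bilinear_matrix(h_in, d[1])
  Ac <- .bilinear_matrix(w_in, d[2])
  out <- array(0, dim = c(h_in, w_in, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- t(Ar) %*% g[, , c] %*% Ac
  if (was_mat) out[, , 1] else out
}

# Nearest-neighbour resize; preserves the value set (and storage mode),
# hence safe for integer class masks.
.resize_nearest <- function(x, h_out, w_out) {
  was_mat <- is.matrix(x)
  x <- .as_hwc(x)
  d <- dim(x)
  ri <- .nearest_index(d[1], h_out)
  ci <- .nearest_index(d[2], w_out)
  out <- x[ri, ci, , drop = FALSE]
  if (was_mat) out[, , 1] else out
}

# Separable Gaussian blur with a truncated, border-renormalised kernel.
.gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  blur_mat <- function(n) {
    key <- sprintf("g_%d_%g", n, sigma)
    hit <- .interp_cache[[key]]
    if (!is.null(hit)) return(hit)
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    B <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      j <- seq_len(n) + off
      ok <- j >= 1 & j <= n
      B[cbind(which(ok), j[ok])] <- B[cbind(which(ok), j[ok])] + k[off + r + 1]
    }
    B <- B / rowSums(B)
    .interp_cache[[key]] <- B
    B
  }
  Br <- blur_mat(nrow(x))
  Bc <- blur_mat(ncol(x))
  Br %*% x %*% t(Bc)
}

# Concatenate two H x W x C arrays along the channel axis (column-major
# slices are contiguous, so c() does the right thing).
.cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

.check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}
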
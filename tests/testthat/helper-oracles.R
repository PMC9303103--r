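# Independent brute-force oracles: naive double-loop implementations of the
# channel-wise distillation, cross-entropy and Dice losses, kept deliberately
# free of any vectorized code shared with the package internals.

oracle_channel_softmax <- function(logits, tau, support = NULL) {
  d <- dim(logits)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (is.null(support)) support <- matrix(1, H, W)
  out <- array(0, d)
  for (c in seq_len(C)) {
    den <- 0
    for (i in seq_len(H)) for (j in seq_len(W))
      if (support[i, j] > 0) den <- den + exp(logits[i, j, c] / tau)
    for (i in seq_len(H)) for (j in seq_len(W))
      if (support[i, j] > 0) out[i, j, c] <- exp(logits[i, j, c] / tau) / den
  }
  out
}

oracle_kd_loss <- function(teacher, student, tau, support = NULL) {
  d <- dim(teacher)
  if (is.null(support)) support <- matrix(1, d[1], d[2])
  pt <- oracle_channel_softmax(teacher, tau, support)
  ps <- oracle_channel_softmax(student, tau, support)
  acc <- 0
  for (c in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    if (support[i, j] > 0 && pt[i, j, c] > 0)
      acc <- acc + pt[i, j, c] * log(pt[i, j, c] / ps[i, j, c])
  tau^2 / d[3] * acc
}

oracle_ce_loss <- function(gt, logits) {
  d <- dim(logits)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    den <- 0
    for (c in seq_len(d[3])) den <- den + exp(logits[i, j, c])
    p <- exp(logits[i, j, gt[i, j] + 1]) / den
    acc <- acc - log(p)
  }
  acc / (d[1] * d[2])
}

oracle_dice_loss <- function(gt, logits, smooth = 1e-6) {
  d <- dim(logits)
  total <- 0
  for (c in seq_len(d[3])) {
    inter <- 0; psum <- 0; gsum <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      den <- 0
      for (cc in seq_len(d[3])) den <- den + exp(logits[i, j, cc])
      p <- exp(logits[i, j, c]) / den
      g <- as.numeric(gt[i, j] == c - 1)
      inter <- inter + p * g; psum <- psum + p; gsum <- gsum + g
    }
    total <- total + (2 * inter + smooth) / (psum + gsum + smooth)
  }
  1 - total / d[3]
}

random_logits <- function(H, W, C, scale = 2) {
  array(stats::rnorm(H * W * C, sd = scale), c(H, W, C))
}
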
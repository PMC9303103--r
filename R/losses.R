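#' Loss weights for the combined segmentation objective
#'
#' The training objective is
#' \deqn{L = \alpha L_{CE} + \beta L_{Dice} + \gamma L_{KD},}
#' where the distillation term compares teacher and student channel-wise
#' spatial distributions at temperature \eqn{\tau}. Teachers train with
#' \eqn{\gamma = 0}; the distilled student uses \eqn{\gamma = 3, \tau = 4}.
#'
#' @param alpha Cross-entropy weight (>= 0).
#' @param beta Dice weight (>= 0).
#' @param gamma Distillation weight (>= 0).
#' @param tau Distillation temperature (> 0).
#' @return A \code{cw_loss_weights} list.
#' @export
loss_weights <- function(alpha = 1, beta = 1, gamma = 0, tau = 4) {
  stopifnot(is.finite(alpha), alpha >= 0, is.finite(beta), beta >= 0,
            is.finite(gamma), gamma >= 0, is.finite(tau), tau > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau = tau),
            class = "cw_loss_weights")
}

.logits_dims <- function(logits) {
  d <- dim(logits)
  if (is.null(d) || length(d) != 3)
    stop("logits must be an H x W x C array", call. = FALSE)
  if (d[3] < 1) stop("logits need at least one channel", call. = FALSE)
  d
}

# Channel-wise log-softmax over pixels, optionally restricted to a support
# set; returns a P x C matrix with -Inf outside the support.
.channel_logsoftmax <- function(logits, tau, support = NULL) {
  d <- .logits_dims(logits)
  .check_finite(logits, "logits")
  P <- d[1] * d[2]
  z <- matrix(logits, P, d[3]) / tau
  if (!is.null(support)) {
    sv <- as.logical(support)
    if (length(sv) != P) stop("support size mismatch", call. = FALSE)
    if (!any(sv)) stop("empty support mask", call. = FALSE)
    z[!sv, ] <- -Inf
  }
  m <- apply(z, 2, max)
  lse <- m + log(colSums(exp(sweep(z, 2, m, "-"))))
  sweep(z, 2, lse, "-")
}

#' Channel-wise spatial softmax
#'
#' Converts each class channel of a logits map into a probability
#' distribution over its W*H pixel locations:
#' \deqn{\phi(y)_{c,i} = \exp(y_{c,i}/\tau) / \sum_{i'} \exp(y_{c,i'}/\tau).}
#' This spatial (within-channel) softmax is deliberately distinct from the
#' per-pixel softmax across classes used by the cross-entropy and Dice
#' losses. Computed with max-subtraction for numerical stability.
#'
#' @param logits H x W x C array of logits.
#' @param tau Temperature (> 0).
#' @param support Optional H x W binary mask; normalization then runs over
#'   supported pixels only and the result is 0 elsewhere.
#' @return H x W x C array; each channel sums to 1 over the support.
#' @export
channel_softmax <- function(logits, tau = 1, support = NULL) {
  stopifnot(is.finite(tau), tau > 0)
  d <- .logits_dims(logits)
  ls <- .channel_logsoftmax(logits, tau, support)
  p <- exp(ls)
  array(p, dim = d)
}

#' Channel-wise knowledge-distillation loss
#'
#' KL divergence between teacher and student channel-wise spatial
#' distributions, summed over channels and pixels and scaled by
#' \eqn{\tau^2 / C}:
#' \deqn{L_{KD} = \frac{\tau^2}{C} \sum_{c=1}^{C} \sum_{i=1}^{W H}
#'   \phi(y^T)_{c,i} \log\frac{\phi(y^T)_{c,i}}{\phi(y^S)_{c,i}}.}
#' The teacher distribution is a constant target (no gradient is defined
#' with respect to it).
#'
#' @param teacher,student H x W x C logit arrays of identical shape.
#' @param tau Temperature.
#' @param support Optional H x W binary mask restricting both the softmax
#'   normalization and the sum to supported pixels (used when the teacher's
#'   logits only exist inside a restored ROI).
#' @return Non-negative scalar; 0 iff the per-channel distributions agree.
#' @export
kd_loss <- function(teacher, student, tau = 4, support = NULL) {
  dt <- .logits_dims(teacher); ds <- .logits_dims(student)
  if (!identical(dt, ds)) stop("teacher/student shape mismatch", call. = FALSE)
  lt <- .channel_logsoftmax(teacher, tau, support)
  ls <- .channel_logsoftmax(student, tau, support)
  pt <- exp(lt)
  terms <- pt * (lt - ls)
  terms[pt == 0] <- 0 # outside support (and exact zeros): 0 * log(...) := 0
  tau^2 / dt[3] * sum(terms)
}

# Gradient of kd_loss with respect to the student logits:
# (tau / C) * (phi(y^S) - phi(y^T)) on the support, 0 elsewhere.
.kd_grad <- function(teacher, student, tau, support = NULL) {
  d <- .logits_dims(student)
  pt <- exp(.channel_logsoftmax(teacher, tau, support))
  ps <- exp(.channel_logsoftmax(student, tau, support))
  array((tau / d[3]) * (ps - pt), dim = d)
}

# Per-pixel softmax across classes (P x C), numerically stable.
.pixel_softmax <- function(logits) {
  d <- .logits_dims(logits)
  .check_finite(logits, "logits")
  lm <- matrix(logits, d[1] * d[2], d[3])
  mx <- lm[, 1]
  if (d[3] > 1) for (c in 2:d[3]) mx <- pmax(mx, lm[, c])
  e <- exp(lm - mx)
  e / rowSums(e)
}

.check_gt <- function(gt, d) {
  if (!all(dim(gt) == d[1:2])) stop("mask/logits shape mismatch", call. = FALSE)
  if (any(gt < 0) || any(gt >= d[3]))
    stop("mask contains class ids outside 0..", d[3] - 1, call. = FALSE)
  invisible(TRUE)
}

#' Pixel-wise cross-entropy loss
#'
#' Mean over pixels of the negative log per-pixel softmax probability of the
#' true class (softmax across the C classes at each pixel).
#'
#' @param gt H x W integer mask with class ids in 0..C-1.
#' @param logits H x W x C logit array.
#' @return Non-negative scalar.
#' @export
ce_loss <- function(gt, logits) {
  d <- .logits_dims(logits)
  .check_gt(gt, d)
  lm <- matrix(logits, d[1] * d[2], d[3])
  mx <- lm[, 1]
  if (d[3] > 1) for (c in 2:d[3]) mx <- pmax(mx, lm[, c])
  lse <- mx + log(rowSums(exp(lm - mx)))
  picked <- lm[cbind(seq_len(nrow(lm)), as.integer(gt) + 1L)]
  mean(lse - picked)
}

.ce_grad <- function(gt, logits) {
  d <- .logits_dims(logits)
  .check_gt(gt, d)
  p <- .pixel_softmax(logits)
  P <- nrow(p)
  p[cbind(seq_len(P), as.integer(gt) + 1L)] <-
    p[cbind(seq_len(P), as.integer(gt) + 1L)] - 1
  array(p / P, dim = d)
}

#' Multi-class soft Dice loss
#'
#' One minus the mean over all C classes (background included) of the soft
#' Dice coefficient between the per-pixel softmax probabilities and the
#' one-hot ground truth, with additive smoothing.
#'
#' @inheritParams ce_loss
#' @param smooth Smoothing constant added to numerator and denominator.
#' @return Scalar in [0, 1].
#' @export
dice_loss <- function(gt, logits, smooth = 1e-6) {
  d <- .logits_dims(logits)
  .check_gt(gt, d)
  p <- .pixel_softmax(logits)
  gidx <- as.integer(gt) + 1L
  inter <- num <- numeric(d[3])
  for (c in seq_len(d[3])) {
    gc <- gidx == c
    inter[c] <- sum(p[gc, c])
    num[c] <- sum(p[, c]) + sum(gc)
  }
  1 - mean((2 * inter + smooth) / (num + smooth))
}

.dice_grad <- function(gt, logits, smooth = 1e-6) {
  d <- .logits_dims(logits)
  .check_gt(gt, d)
  p <- .pixel_softmax(logits)
  P <- nrow(p); C <- d[3]
  gidx <- as.integer(gt) + 1L
  gmat <- matrix(0, P, C)
  gmat[cbind(seq_len(P), gidx)] <- 1
  inter <- colSums(p * gmat)
  den <- colSums(p) + colSums(gmat)
  # dL/dp_{ic} = -(1/C) * (2 g_{ic} (den+s) - (2 inter + s)) / (den+s)^2
  a <- 2 / (den + smooth)
  bq <- (2 * inter + smooth) / (den + smooth)^2
  dLdp <- -(sweep(gmat, 2, a, "*") - matrix(bq, P, C, byrow = TRUE)) / C
  # back through the per-pixel softmax
  dz <- p * (dLdp - rowSums(dLdp * p))
  array(dz, dim = d)
}

#' Combined training objective
#'
#' \eqn{\alpha L_{CE} + \beta L_{Dice} + \gamma L_{KD}}, returning the total
#' and the three components for logging. The teacher logits are required
#' exactly when \eqn{\gamma > 0}.
#'
#' @inheritParams ce_loss
#' @param student_logits H x W x C student logits.
#' @param teacher_logits Optional H x W x C teacher logits (constant target).
#' @param weights A [loss_weights()].
#' @param support Optional H x W binary mask passed to [kd_loss()].
#' @return List with \code{total}, \code{ce}, \code{dice}, \code{kd}.
#' @export
combined_loss <- function(gt, student_logits, teacher_logits = NULL,
                          weights = loss_weights(), support = NULL) {
  stopifnot(inherits(weights, "cw_loss_weights"))
  if (weights$gamma > 0 && is.null(teacher_logits))
    stop("gamma > 0 requires teacher logits", call. = FALSE)
  ce <- ce_loss(gt, student_logits)
  dc <- dice_loss(gt, student_logits)
  kd <- if (weights$gamma > 0)
    kd_loss(teacher_logits, student_logits, weights$tau, support) else 0
  list(total = weights$alpha * ce + weights$beta * dc + weights$gamma * kd,
       ce = ce, dice = dc, kd = kd)
}

# Gradient of combined_loss with respect to the student logits.
.combined_grad <- function(gt, student_logits, teacher_logits = NULL,
                           weights = loss_weights(), support = NULL) {
  g <- weights$alpha * .ce_grad(gt, student_logits) +
    weights$beta * .dice_grad(gt, student_logits)
  if (weights$gamma > 0)
    g <- g + weights$gamma * .kd_grad(teacher_logits, student_logits,
                                      weights$tau, support)
  g
}
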
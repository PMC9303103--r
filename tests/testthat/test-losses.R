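test_that("channel softmax matches its definition and worked examples", {
  # constant logits: uniform 1/(W*H) in every channel
  lg <- array(1.7, c(3, 5, 2))
  p <- channel_softmax(lg, tau = 2.3)
  expect_equal(as.vector(p), rep(1 / 15, 30))
  # single channel, 1x2 logits [0, ln 3], tau = 1 -> [0.25, 0.75]
  lg <- array(c(0, log(3)), c(1, 2, 1))
  expect_equal(as.vector(channel_softmax(lg, 1)), c(0.25, 0.75))
  # high-temperature limit approaches uniform
  lg <- random_logits(4, 4, 3)
  p <- channel_softmax(lg, tau = 1e6)
  expect_equal(as.vector(p), rep(1 / 16, 48), tolerance = 1e-4)
})

test_that("channel softmax normalizes per channel and ignores per-channel shifts", {
  set.seed(101)
  for (rep in 1:25) {
    lg <- random_logits(sample(2:5, 1), sample(2:5, 1), sample(1:4, 1))
    tau <- runif(1, 0.5, 8)
    p <- channel_softmax(lg, tau)
    expect_equal(apply(p, 3, sum), rep(1, dim(lg)[3]), tolerance = 1e-6)
    shift <- rnorm(dim(lg)[3])
    lg2 <- sweep(lg, 3, shift, "+")
    expect_equal(channel_softmax(lg2, tau), p, tolerance = 1e-12)
  }
})

test_that("kd loss reproduces the hand-computed KL example and vanishes at identity", {
  t <- array(c(0, log(3)), c(1, 2, 1))
  s <- array(0, c(1, 2, 1))
  expect_equal(kd_loss(t, s, tau = 1),
               0.25 * log(0.25 / 0.5) + 0.75 * log(0.75 / 0.5),
               tolerance = 1e-12)
  set.seed(7)
  lg <- random_logits(3, 4, 3)
  for (tau in c(0.7, 1, 4)) expect_equal(kd_loss(lg, lg, tau), 0)
})

test_that("losses match brute-force double-loop oracles on random tensors", {
  set.seed(202)
  for (rep in 1:30) {
    H <- sample(2:4, 1); W <- sample(2:4, 1); C <- sample(2:4, 1)
    t <- random_logits(H, W, C); s <- random_logits(H, W, C)
    tau <- runif(1, 0.5, 6)
    gt <- matrix(sample(0:(C - 1), H * W, TRUE), H, W)
    expect_equal(kd_loss(t, s, tau), oracle_kd_loss(t, s, tau),
                 tolerance = 1e-10)
    expect_equal(ce_loss(gt, s), oracle_ce_loss(gt, s), tolerance = 1e-10)
    expect_equal(dice_loss(gt, s), oracle_dice_loss(gt, s), tolerance = 1e-10)
    sup <- matrix(rbinom(H * W, 1, 0.6), H, W)
    if (any(sup > 0))
      expect_equal(kd_loss(t, s, tau, sup), oracle_kd_loss(t, s, tau, sup),
                   tolerance = 1e-10)
  }
})

test_that("cross-entropy hits its closed forms", {
  # uniform logits over 4 classes -> ln 4
  gt <- matrix(sample(0:3, 36, TRUE), 6, 6)
  expect_equal(ce_loss(gt, array(0, c(6, 6, 4))), log(4))
  # strongly confident correct prediction -> ~0
  lg <- array(0, c(6, 6, 4))
  for (c in 1:4) lg[, , c] <- (gt == c - 1) * 50
  expect_lt(ce_loss(gt, lg), 1e-10)
})

test_that("dice loss is 0 for confident-correct and ~1 per missed class", {
  gt <- matrix(0L, 6, 6); gt[2:4, 2:4] <- 1L
  lg <- array(0, c(6, 6, 2))
  lg[, , 1] <- (gt == 0) * 60; lg[, , 2] <- (gt == 1) * 60
  expect_lt(dice_loss(gt, lg), 1e-6)
  # everything predicted background while gt has foreground:
  # background term ~ fine, foreground term -> 1, so loss -> 1/2 for C = 2
  lg0 <- array(0, c(6, 6, 2)); lg0[, , 1] <- 60
  d <- dice_loss(gt, lg0)
  expect_gt(d, 0.25)
  expect_lt(abs((1 - d) - 0.5 * 2 * 27 / (27 + 36)), 0.02)
})

test_that("combined loss is the weighted component sum and is linear in the weights", {
  set.seed(33)
  lg <- random_logits(4, 4, 4); tch <- random_logits(4, 4, 4)
  gt <- matrix(sample(0:3, 16, TRUE), 4, 4)
  w <- loss_weights(1, 1, 3, 4)
  out <- combined_loss(gt, lg, tch, w)
  expect_equal(out$total,
               ce_loss(gt, lg) + dice_loss(gt, lg) + 3 * kd_loss(tch, lg, 4),
               tolerance = 1e-12)
  w2 <- loss_weights(0.3, 1.7, 0.9, 4)
  out2 <- combined_loss(gt, lg, tch, w2)
  expect_equal(out2$total, 0.3 * out$ce + 1.7 * out$dice + 0.9 * out$kd,
               tolerance = 1e-12)
  # gamma = 0: teacher ignored, pure CE + Dice
  w0 <- loss_weights(1, 1, 0, 4)
  expect_equal(combined_loss(gt, lg, NULL, w0)$total, out$ce + out$dice)
  expect_equal(combined_loss(gt, lg, tch, w0)$total,
               combined_loss(gt, lg, NULL, w0)$total)
  # alpha = beta = 0, gamma = 1: KD alone
  expect_equal(combined_loss(gt, lg, tch, loss_weights(0, 0, 1, 4))$total,
               out$kd)
  expect_error(combined_loss(gt, lg, NULL, w), "teacher")
})

test_that("loss gradients agree with finite differences", {
  set.seed(44)
  H <- 3; W <- 4; C <- 3
  lg <- random_logits(H, W, C); tch <- random_logits(H, W, C)
  gt <- matrix(sample(0:(C - 1), H * W, TRUE), H, W)
  sup <- matrix(1, H, W); sup[1, 1] <- 0
  w <- loss_weights(0.7, 1.3, 2.1, 3)
  g <- cwdistill:::.combined_grad(gt, lg, tch, w, sup)
  eps <- 1e-6
  f <- function(x) combined_loss(gt, x, tch, w, sup)$total
  for (rep in 1:20) {
    i <- sample(length(lg), 1)
    lg2 <- lg; lg2[i] <- lg2[i] + eps
    expect_equal((f(lg2) - f(lg)) / eps, g[i], tolerance = 1e-4)
  }
})

test_that("degenerate loss inputs raise errors", {
  lg <- random_logits(3, 3, 2)
  expect_error(kd_loss(lg, random_logits(3, 4, 2), 1), "mismatch")
  expect_error(kd_loss(lg, lg, 1, support = matrix(0, 3, 3)), "support")
  bad <- lg; bad[1] <- NA
  expect_error(channel_softmax(bad, 1), "finite")
  expect_error(ce_loss(matrix(5L, 3, 3), lg), "class ids")
  expect_error(loss_weights(tau = 0))
  expect_error(loss_weights(alpha = -1))
})
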
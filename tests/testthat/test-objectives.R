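make_onehot <- function(target, P, confidence = 1) {
  d <- dim(target)
  probs <- array((1 - confidence) / (P - 1), c(P, d))
  pm <- matrix(probs, nrow = P)
  pm[cbind(as.vector(target) + 1L, seq_len(length(target)))] <- confidence
  array(pm, c(P, d))
}

test_that("dice loss matches its closed-form cases and the direct oracle", {
  tgt <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  perfect <- make_onehot(tgt, 2)
  expect_lt(dice_loss(perfect, tgt), 1e-5)
  # all mass on the wrong class of a 2-class image: zero overlap everywhere
  wrong <- make_onehot(1L - tgt, 2)
  expect_gt(dice_loss(wrong, tgt), 1 - 1e-5)
  # uniform prediction on a half-foreground image, hand-evaluated
  uni <- array(0.5, c(2, 2, 2))
  expect_equal(dice_loss(uni, tgt), oracle_dice_loss(uni, tgt), tolerance = 1e-12)
  # random probability fields agree with the per-class oracle
  set.seed(21)
  for (P in c(2, 5, 7)) {
    z <- array(rnorm(P * 6 * 6), c(P, 6, 6))
    probs <- oarseg:::softmax_channels(z)
    t2 <- matrix(sample(0:(P - 1), 36, TRUE), 6, 6)
    expect_equal(dice_loss(probs, t2), oracle_dice_loss(probs, t2), tolerance = 1e-12)
  }
  expect_error(dice_loss(make_onehot(tgt, 2), tgt + 5L), "0, P-1")
})

test_that("dice loss is invariant to a common pixel permutation", {
  set.seed(22)
  P <- 3
  probs <- oarseg:::softmax_channels(array(rnorm(P * 16), c(P, 4, 4)))
  tgt <- matrix(sample(0:2, 16, TRUE), 4, 4)
  perm <- sample(16)
  pm <- matrix(probs, nrow = P)[, perm]
  expect_equal(dice_loss(array(pm, c(P, 4, 4)), array(as.vector(tgt)[perm], c(4, 4))),
               dice_loss(probs, tgt), tolerance = 1e-12)
})

test_that("weighted cross-entropy matches closed forms and the oracle", {
  tgt <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_equal(weighted_ce(make_onehot(tgt, 2), tgt, phi = c(1, 1)), 0, tolerance = 1e-9)
  uni <- array(0.5, c(2, 2, 2))
  expect_equal(weighted_ce(uni, tgt, phi = c(1, 1)), log(2), tolerance = 1e-12)
  expect_equal(weighted_ce(uni, tgt, phi = c(2, 2)),
               2 * weighted_ce(uni, tgt, phi = c(1, 1)), tolerance = 1e-12)
  set.seed(23)
  for (rep in 1:5) {
    P <- sample(2:7, 1)
    probs <- oarseg:::softmax_channels(array(rnorm(P * 25), c(P, 5, 5)))
    t2 <- matrix(sample(0:(P - 1), 25, TRUE), 5, 5)
    phi <- runif(P, 0.1, 1)
    expect_equal(weighted_ce(probs, t2, phi), oracle_weighted_ce(probs, t2, phi),
                 tolerance = 1e-6)
  }
  expect_error(weighted_ce(uni, tgt, phi = c(-1, 1)), "phi")
})

test_that("combined loss is the stated linear combination", {
  set.seed(24)
  P <- 5
  probs <- oarseg:::softmax_channels(array(rnorm(P * 64), c(P, 8, 8)))
  tgt <- matrix(sample(0:(P - 1), 64, TRUE), 8, 8)
  phi <- c(0.2, 0.5, 0.5, 0.5, 0.5)
  only_dice <- loss_weights(1, 0, phi)
  only_ce <- loss_weights(0, 1, phi)
  both <- loss_weights(0.9, 0.1, phi)
  expect_equal(combined_loss(probs, tgt, only_dice), dice_loss(probs, tgt))
  expect_equal(combined_loss(probs, tgt, only_ce), weighted_ce(probs, tgt, phi))
  expect_equal(combined_loss(probs, tgt, both),
               0.9 * dice_loss(probs, tgt) + 0.1 * weighted_ce(probs, tgt, phi),
               tolerance = 1e-12)
  expect_gte(combined_loss(probs, tgt, both), 0)
  # zero exactly at a perfect confident prediction
  expect_lt(combined_loss(make_onehot(tgt, P), tgt, both), 1e-5)
})

test_that("published default weights are exposed per configuration", {
  w4 <- default_loss_weights("segthor")
  expect_equal(w4$theta, 0.9)
  expect_equal(w4$sigma, 0.1)
  expect_equal(w4$phi, c(0.2, 0.5, 0.5, 0.5, 0.5))
  w6 <- default_loss_weights("structseg")
  expect_equal(w6$phi, c(0.1, 0.2, 0.2, 0.3, 0.4, 0.4, 0.4))
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(25)
  P <- 3
  logits <- array(rnorm(P * 9), c(P, 3, 3))
  tgt <- matrix(sample(0:2, 9, TRUE), 3, 3)
  wts <- loss_weights(0.9, 0.1, c(0.3, 0.5, 0.7))
  g <- oarseg:::combined_loss_grad(logits, tgt, wts)
  expect_equal(g$loss, 0.9 * g$dice + 0.1 * g$ce)
  eps <- 1e-5
  idx <- sample(length(logits), 10)
  for (i in idx) {
    zp <- logits; zp[i] <- zp[i] + eps
    zm <- logits; zm[i] <- zm[i] - eps
    fd <- (combined_loss(oarseg:::softmax_channels(zp), tgt, wts) -
           combined_loss(oarseg:::softmax_channels(zm), tgt, wts)) / (2 * eps)
    expect_equal(g$grad[i], fd, tolerance = 1e-6)
  }
})
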
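test_that("unanimous raters are reproduced exactly", {
  set.seed(41)
  m <- random_mask(c(10, 10, 4))
  stack <- rater_stack(list(m, m, m), dim = dim(m))
  res <- staple_binary(stack)
  expect_equal(res$fused, as.numeric(as.vector(m)))
  expect_true(all(res$posterior[as.vector(m)] >= 0.5))
  expect_true(all(res$posterior[!as.vector(m)] < 0.5))
})

test_that("a 2-vs-1 voxel vote yields posterior above one half", {
  # symmetric raters (p = q), uniform prior 0.5: the E-step reduces to
  # p^2(1-p) vs p(1-p)^2 in favour of foreground
  D <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1, 1), nrow = 3, byrow = FALSE)
  # voxel 1: raters 1,2 mark it, rater 3 does not; plus background/fg anchors
  cfg <- fusion_config(prior = 0.5, init_pq = 0.9, max_iter = 1)
  res <- staple_binary(rater_stack(D), cfg)
  expect_gt(res$posterior[1], 0.5)
  # hand-evaluated E-step with p = q = 0.9:
  a <- 0.5 * 0.9 * 0.9 * 0.1
  b <- 0.5 * 0.1 * 0.1 * 0.9
  expect_equal(res$posterior[1], a / (a + b), tolerance = 1e-12)
})

test_that("EM log-likelihood is monotone and rater order is irrelevant", {
  set.seed(42)
  gt <- random_mask(c(20, 20, 8))
  stack <- simulate_raters(gt, rater_spec(p = c(0.95, 0.8, 0.9),
                                          q = c(0.98, 0.99, 0.9), seed = 7))
  res <- staple_binary(stack)
  expect_true(all(diff(res$log_likelihood) > -1e-6))
  expect_true(res$iterations <= 100)
  perm <- c(3, 1, 2)
  res2 <- staple_binary(rater_stack(stack$decisions[perm, ], dim = stack$dim))
  expect_equal(res2$posterior, res$posterior, tolerance = 1e-9)
  expect_equal(res2$sensitivity, res$sensitivity[perm], tolerance = 1e-9)
  expect_equal(res2$specificity, res$specificity[perm], tolerance = 1e-9)
})

test_that("STAPLE recovers the simulated sensitivities and specificities", {
  p_true <- c(0.95, 0.80, 0.90)
  q_true <- c(0.98, 0.99, 0.90)
  gt <- array(FALSE, c(40, 40, 12))
  gt[12:28, 12:28, 3:10] <- TRUE  # ~2300 fg voxels in V = 19200
  set.seed(43)
  errs <- replicate(20, {
    seed <- sample.int(1e6, 1)
    stack <- simulate_raters(gt, rater_spec(p_true, q_true, seed = seed))
    res <- staple_binary(stack)
    c(mean(abs(res$sensitivity - p_true)), mean(abs(res$specificity - q_true)))
  })
  expect_lte(mean(errs[1, ]), 0.03)
  expect_lte(mean(errs[2, ]), 0.03)
})

test_that("majority voting follows the strict-majority tie-to-background rule", {
  # all 2^3 patterns for 3 raters
  pats <- expand.grid(0:1, 0:1, 0:1)
  D <- t(as.matrix(pats))
  mv <- majority_vote(rater_stack(D))
  expect_equal(mv, as.numeric(colSums(D) >= 2))
  # 2-2 tie with four raters goes to background
  D4 <- matrix(c(1, 1, 0, 0), ncol = 1)
  expect_equal(majority_vote(rater_stack(D4)), 0)
  # unanimity reproduces any rater
  D5 <- matrix(rep(c(1, 0, 1), 3), nrow = 3, byrow = TRUE)
  expect_equal(majority_vote(rater_stack(D5)), c(1, 0, 1))
})

test_that("multi-class fusion reassembles per-class STAPLE posteriors", {
  ph <- make_phantom(phantom_spec(seed = 44))
  lv <- ph$labels
  # identical raters: output identical to input
  fused <- fuse_multiclass(list(lv, lv, lv))
  expect_identical(fused$labels, lv$labels)
  # spatially disjoint classes fuse exactly as isolated binary STAPLE runs
  set.seed(44)
  vols <- lapply(1:3, function(i) {
    arr <- array(0L, dim = dim(lv$labels))
    m1 <- simulate_raters(lv$labels == 1, rater_spec(c(0.9, 0.85), c(0.99, 0.99), seed = i))
    m2 <- simulate_raters(lv$labels == 2, rater_spec(c(0.9, 0.85), c(0.99, 0.99), seed = i + 50))
    arr[array(m1$decisions[1, ] == 1, dim(arr))] <- 1L
    arr[array(m2$decisions[1, ] == 1, dim(arr)) & arr == 0L] <- 2L
    label_volume(arr, lv$spacing, num_classes = 5)
  })
  fused2 <- fuse_multiclass(vols)
  solo <- lapply(1:2, function(cl) {
    Dm <- do.call(rbind, lapply(vols, function(v) as.numeric(v$labels == cl)))
    staple_binary(rater_stack(Dm, dim = dim(lv$labels)))
  })
  for (cl in 1:2) {
    other <- solo[[3 - cl]]$posterior >= 0.5
    # wherever only this class claims the voxel, the joint reassembly equals
    # the isolated binary run exactly; conflicts go to the higher posterior
    expect_equal((fused2$labels == cl)[!other],
                 (solo[[cl]]$fused == 1)[!other])
  }
  expect_error(fuse_multiclass(list(lv)), ">= 2")
})

test_that("STAPLE fusion beats majority voting on heterogeneous raters", {
  # one good, two mediocre, one poor rater: performance weighting should
  # out-score the unweighted vote
  gt <- array(FALSE, c(30, 30, 10))
  gt[8:22, 8:22, 3:8] <- TRUE
  stack <- simulate_raters(gt, rater_spec(p = c(0.98, 0.8, 0.8, 0.65),
                                          q = c(0.99, 0.97, 0.97, 0.9),
                                          seed = 45))
  st <- staple_binary(stack)
  mv <- majority_vote(stack)
  d_st <- dice_score(array(st$fused == 1, dim(gt)), gt)
  d_mv <- dice_score(array(mv == 1, dim(gt)), gt)
  expect_gte(d_st, d_mv)
})

test_that("degenerate stacks are handled without running EM", {
  Dm <- matrix(0, nrow = 3, ncol = 50)
  res <- staple_binary(rater_stack(Dm))
  expect_equal(res$iterations, 0L)
  expect_true(all(res$fused == 0))
  expect_error(rater_stack(matrix(1, 1, 10)), "2 raters")
  expect_error(rater_stack(matrix(2, 3, 4)), "binary")
  expect_error(fusion_config(tol = -1), "tol")
  expect_error(fusion_config(threshold = 1.2), "threshold")
  expect_error(fusion_config(init_pq = 0.4), "init_pq")
})
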
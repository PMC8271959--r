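test_that("decoder stage merges upsample, skip and both branches", {
  set.seed(51)
  ds <- oarseg:::decoder_stage(512 + 256, 256)
  prev <- array(rnorm(512 * 4 * 4), c(512, 4, 4, 1))
  skip <- array(rnorm(256 * 8 * 8), c(256, 8, 8, 1))
  y <- ds$forward(prev, skip)
  expect_equal(dim(y), c(256L, 8L, 8L, 1L))
  # last stage: no skip, double resolution
  ds2 <- oarseg:::decoder_stage(32, 16)
  y2 <- ds2$forward(array(rnorm(32 * 8 * 8), c(32, 8, 8, 1)), NULL)
  expect_equal(dim(y2), c(16L, 8L * 2L, 16L, 1L))
  # spatial mismatch between skip and upsampled previous is an error
  bad_skip <- array(rnorm(256 * 6 * 6), c(256, 6, 6, 1))
  expect_error(ds$forward(prev, bad_skip), "twice")
})

test_that("softmax output is a probability field of the input size", {
  set.seed(52)
  net <- build_network(backbone_spec("resnet34"), num_classes = 7)
  x <- array(rnorm(3 * 64 * 64), c(3, 64, 64))
  p <- network_forward(net, x)
  expect_equal(dim(p), c(7L, 64L, 64L))
  sums <- apply(p, c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p >= 0))
})

test_that("inputs not divisible by 32 are padded and cropped back", {
  set.seed(53)
  net <- build_network(backbone_spec("resnet34"), num_classes = 3)
  x <- array(rnorm(3 * 50 * 70), c(3, 50, 70))
  p <- network_forward(net, x)
  expect_equal(dim(p), c(3L, 50L, 70L))
  sums <- apply(p, c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("group normalization makes inference batch-size independent", {
  set.seed(54)
  net <- build_network(backbone_spec("resnet34"), num_classes = 5)
  xs <- array(rnorm(3 * 64 * 64 * 3), c(3, 64, 64, 3))
  p_batch <- network_forward(net, xs)
  p_solo <- network_forward(net, xs[, , , 1, drop = FALSE])
  expect_lt(max(abs(p_batch[, , , 1] - p_solo[, , , 1])), 1e-6)
  # and repeated forwards are deterministic
  p_again <- network_forward(net, xs[, , , 1, drop = FALSE])
  expect_identical(p_solo, p_again)
})

test_that("one optimisation step decreases the loss on a synthetic slice", {
  set.seed(55)
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 4L),
                                  organs = list(list(class = 1L, primitive = "tube",
                                                     center = c(16, 16), radius = 4,
                                                     mean_hu = 200, wobble = 0)),
                                  num_classes = 2L, seed = 55))
  img <- normalize_hu(ph$image, default_window("segthor"))
  x <- to_model_input(img$voxels[, , 2])
  dim(x) <- c(dim(x), 1L)
  tgt <- array(ph$labels$labels[, , 2], c(32, 32, 1))
  net <- build_network(backbone_spec("resnet34"), num_classes = 2)
  wts <- loss_weights(0.9, 0.1, c(0.2, 0.5))
  opt <- oarseg:::adam_optimizer(net, lr = 1e-3)
  z0 <- oarseg:::forward_logits(net, x, train = TRUE)
  g0 <- oarseg:::combined_loss_grad(z0, tgt, wts)
  oarseg:::backward_logits(net, g0$grad)
  oarseg:::adam_step(opt)
  z1 <- oarseg:::forward_logits(net, x, train = TRUE)
  g1 <- oarseg:::combined_loss_grad(z1, tgt, wts)
  expect_lt(g1$loss, g0$loss)
})

test_that("checkpoints restore the exact forward behaviour", {
  set.seed(56)
  net <- build_network(backbone_spec("resnet34"), num_classes = 5)
  x <- array(rnorm(3 * 64 * 64), c(3, 64, 64))
  p1 <- network_forward(net, x)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, tmp, window = default_window("segthor"),
                  extra = list(note = "test"))
  ck <- load_checkpoint(tmp)
  expect_equal(ck$window$lower, -400)
  expect_equal(ck$extra$note, "test")
  p2 <- network_forward(ck$net, x)
  expect_equal(p2, p1, tolerance = 1e-12)
})

test_that("network construction validates its arguments", {
  expect_error(build_network(num_classes = 1), ">= 2")
  expect_error(backbone_spec("vgg16"))
  expect_error(norm_spec(groups = 0), "positive")
})
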
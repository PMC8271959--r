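test_that("channel summary gate has the documented shape and values", {
  f <- array(0, c(64, 32, 32))
  g <- channel_summary(f)
  expect_equal(dim(g), c(64L, 1L, 1L))
  expect_true(all(g == 0.5))  # sigmoid(0 + 0)
  f1 <- array(1, c(1, 4, 4))  # mean 1, max 1
  expect_equal(channel_summary(f1)[1], 1 / (1 + exp(-2)))
})

test_that("spatial attention map is a [0,1] field of the input size", {
  set.seed(11)
  f <- array(rnorm(64 * 32 * 32), c(64, 32, 32))
  a <- spatial_attention_map(f)
  expect_equal(dim(a), c(1L, 32L, 32L))
  expect_true(all(a >= 0 & a <= 1))
  # zero input and zero-initialised conv bias give a uniform 0.5 gate
  a0 <- spatial_attention_map(array(0, c(8, 16, 16)))
  expect_true(all(abs(a0 - 0.5) < 1e-12))
  expect_error(sam_block(kernel = 4), "odd")
})

test_that("SAM preserves shape and never amplifies", {
  set.seed(12)
  f <- array(rnorm(16 * 20 * 24), c(16, 20, 24))
  y <- apply_sam(f)
  expect_equal(dim(y), dim(f))
  expect_true(all(abs(y) <= abs(f) + 1e-12))
  # with both gates saturated at ~1 SAM approaches the identity
  sat <- sam_block(7)
  sat$conv$W[] <- 0
  sat$conv$b[] <- 1e4
  fbig <- array(50, c(4, 8, 8))  # spatial mean+max = 100 -> channel gate ~ 1
  expect_equal(apply_sam(fbig, sam = sat), fbig, tolerance = 1e-8)
})

test_that("ASPP preserves spatial size and sets the channel count", {
  set.seed(13)
  ap <- aspp_block(32, 32, rates = c(6, 12, 18))
  x <- array(rnorm(32 * 16 * 16), c(32, 16, 16, 1))
  y <- ap$forward(x)
  expect_equal(dim(y), c(32L, 16L, 16L, 1L))
  ap2 <- aspp_block(8, 12, rates = 1)
  y2 <- ap2$forward(array(rnorm(8 * 9 * 7), c(8, 9, 7, 1)))
  expect_equal(dim(y2), c(12L, 9L, 7L, 1L))
  expect_error(aspp_block(8, 8, rates = integer(0)), "non-empty")
})

test_that("dilated convolution has the expected receptive field", {
  # a rate-r 3x3 branch reaches exactly r voxels out per axis: an impulse
  # response confined to offsets {-r, 0, r}
  r <- 3L
  cv <- oarseg:::conv_layer(1, 1, 3, dilation = r, pad = r)
  cv$W[] <- 1
  x <- array(0, c(1, 15, 15, 1))
  x[1, 8, 8, 1] <- 1
  y <- cv$forward(x)
  nz <- which(y[1, , , 1] != 0, arr.ind = TRUE)
  expect_setequal(unique(as.vector(nz - 8)), c(-r, 0L, r))
  expect_equal(max(abs(nz - 8)), r)
})
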
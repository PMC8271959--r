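test_that("phantom generation is fully determined by the seed", {
  a <- make_phantom(phantom_spec(seed = 5))
  b <- make_phantom(phantom_spec(seed = 5))
  cc <- make_phantom(phantom_spec(seed = 6))
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_false(identical(a$image$voxels, cc$image$voxels))
})

test_that("tube voxel count sits in the analytic cylinder band", {
  organs <- list(list(class = 1L, primitive = "tube", center = c(32, 32),
                      radius = 2, mean_hu = 60, wobble = 0))
  ph <- make_phantom(phantom_spec(organs = organs, seed = 1))
  v <- sum(ph$labels$labels == 1L)
  expect_gte(v, pi * 2^2 * 16 * 0.7)
  expect_lte(v, pi * 3^2 * 16 * 1.3)
})

test_that("organ contrast is exact in the noise-free phantom", {
  organs <- list(list(class = 1L, primitive = "tube", center = c(32, 32),
                      radius = 3, mean_hu = 130, wobble = 0))
  ph <- make_phantom(phantom_spec(organs = organs, noise_sd = 0,
                                  background_hu = 30, seed = 2))
  fg <- ph$image$voxels[ph$labels$labels == 1L]
  bg <- ph$image$voxels[ph$labels$labels == 0L]
  expect_equal(mean(fg) - mean(bg), 100)
})

test_that("labels and windowed intensities stay consistent under noise", {
  ph <- make_phantom(phantom_spec(seed = 8))  # esophagus analog: +30 HU
  win <- default_window("segthor")
  img <- normalize_hu(ph$image, win)
  fg <- img$voxels[ph$labels$labels == 1L]
  bg <- img$voxels[ph$labels$labels == 0L & abs(ph$image$voxels - 30) < 100]
  contrast <- 30 / (win$upper - win$lower)
  expect_equal(mean(fg) - mean(bg), contrast, tolerance = 0.25 * contrast)
})

test_that("simulated raters realise the Bernoulli sensitivity model", {
  gt <- array(FALSE, c(40, 40, 10))
  gt[10:30, 10:30, 2:9] <- TRUE
  rs <- rater_spec(p = c(1, 1), q = c(1, 1), seed = 1)
  stack <- simulate_raters(gt, rs)
  expect_equal(stack$decisions[1, ], as.numeric(as.vector(gt)))
  expect_equal(stack$decisions[2, ], as.numeric(as.vector(gt)))
  # p = 0.9: agreement on foreground within 3 binomial sd
  rs2 <- rater_spec(p = c(0.9, 0.8), q = c(0.95, 0.99), seed = 2)
  st2 <- simulate_raters(gt, rs2)
  vfg <- sum(gt)
  agree <- mean(st2$decisions[1, as.vector(gt)] == 1)
  expect_lt(abs(agree - 0.9), 3 * sqrt(0.9 * 0.1 / vfg))
  # determinism
  st3 <- simulate_raters(gt, rs2)
  expect_identical(st2$decisions, st3$decisions)
  expect_error(rater_spec(p = c(0.4, 0.9), q = c(0.9, 0.9)), "0.5")
  expect_error(simulate_raters(array(TRUE, c(3, 3, 3)), rs2), "foreground and background")
})

test_that("phantom datasets vary by patient and are reproducible", {
  td <- withr::local_tempdir()
  dat <- write_phantom_dataset(td, n_patients = 2, seed = 99)
  expect_equal(nrow(dat), 2)
  v1 <- read_volume(dat$image[1]); v2 <- read_volume(dat$image[2])
  expect_false(identical(v1$voxels, v2$voxels))
  l1 <- read_volume(dat$labels[1], labels = TRUE, num_classes = 5)
  expect_setequal(sort(unique(as.vector(l1$labels))), 0:4)
  td2 <- withr::local_tempdir()
  dat2 <- write_phantom_dataset(td2, n_patients = 2, seed = 99)
  expect_identical(read_volume(dat2$image[1])$voxels, v1$voxels)
})
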
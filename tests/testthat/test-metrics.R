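test_that("dice score follows the overlap formula and empty-mask conventions", {
  a <- array(FALSE, c(3, 3, 1)); a[1:2, 1, 1] <- TRUE            # |T| = 2
  b <- array(FALSE, c(3, 3, 1)); b[1:2, 1, 1] <- TRUE; b[1:2, 2, 1] <- TRUE  # |N| = 4
  expect_equal(dice_score(a, b), 2 * 2 / (2 + 4))
  expect_equal(dice_score(b, a), dice_score(a, b))  # symmetry
  expect_equal(dice_score(b, b), 1)
  disj <- array(FALSE, c(3, 3, 1)); disj[3, 3, 1] <- TRUE
  expect_equal(dice_score(a, disj), 0)
  empty <- array(FALSE, c(3, 3, 1))
  expect_equal(dice_score(empty, empty), 1)
  expect_equal(dice_score(a, empty), 0)
  expect_error(dice_score(a, array(FALSE, c(2, 2, 1))), "mismatch")
})

test_that("surface extraction finds exactly the face-connected boundary", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(extract_surface(binary_mask(one)), matrix(c(3, 3, 3), 1), ignore_attr = TRUE)
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(extract_surface(binary_mask(cube))), 26)  # all but the centre
  full <- array(TRUE, c(3, 4, 2))  # every voxel touches the grid border
  expect_equal(nrow(extract_surface(binary_mask(full))), 24)
  expect_error(extract_surface(binary_mask(array(FALSE, c(2, 2, 2)))), "empty")
  # spacing scales coordinates
  s <- extract_surface(binary_mask(one, spacing = c(2, 3, 4)))
  expect_equal(as.vector(s), c(6, 9, 12))
})

test_that("hausdorff distance matches hand-computed geometry", {
  a <- array(FALSE, c(8, 8, 4)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(8, 8, 4)); b[4, 5, 1] <- TRUE  # offset (3,4,0)
  expect_equal(hausdorff(a, b, 100), 5)
  expect_equal(hausdorff(a, a, 100), 0)
  expect_true(is.na(hausdorff(a, array(FALSE, c(8, 8, 4)))))
  expect_error(hausdorff(a, b, percentile = 0), "percentile")
})

test_that("hausdorff agrees exactly with the brute-force oracle", {
  set.seed(31)
  for (rep in 1:100) {
    shape <- c(sample(4:8, 1), sample(4:8, 1), sample(3:5, 1))
    spacing <- runif(3, 0.5, 3)
    t <- random_mask(shape); n <- random_mask(shape)
    if (!any(t) || !any(n)) next
    tm <- binary_mask(t, spacing); nm <- binary_mask(n, spacing)
    expect_equal(hausdorff(tm, nm, 100), oracle_hausdorff(t, n, spacing, 100),
                 tolerance = 1e-9)
    expect_equal(hausdorff(tm, nm, 95), oracle_hausdorff(t, n, spacing, 95),
                 tolerance = 1e-9)
    expect_lte(hausdorff(tm, nm, 95), hausdorff(tm, nm, 100) + 1e-12)
  }
})

test_that("scaling the spacing scales distances and leaves Dice unchanged", {
  set.seed(32)
  t <- random_mask(c(8, 8, 5)); n <- random_mask(c(8, 8, 5))
  sp <- c(1, 1.5, 2)
  s <- 2.5
  h1 <- hausdorff(binary_mask(t, sp), binary_mask(n, sp), 100)
  h2 <- hausdorff(binary_mask(t, s * sp), binary_mask(n, s * sp), 100)
  expect_equal(h2, s * h1, tolerance = 1e-12)
  expect_equal(dice_score(binary_mask(t, sp), binary_mask(n, sp)),
               dice_score(binary_mask(t, s * sp), binary_mask(n, s * sp)))
})

test_that("evaluation table reports one row per foreground class", {
  ph <- make_phantom(phantom_spec(seed = 9))
  tab <- evaluate_segmentation(ph$labels, ph$labels, patient_id = "p")
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$dice == 1))
  expect_true(all(tab$hd == 0))
  # one empty predicted class: Dice 0, surface distance reported missing
  pred <- ph$labels
  pred$labels[pred$labels == 3L] <- 0L
  tab2 <- evaluate_segmentation(pred, ph$labels)
  expect_equal(tab2$dice[tab2$class == 3], 0)
  expect_true(is.na(tab2$hd[tab2$class == 3]))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(tab2, tmp)
  expect_equal(nrow(utils::read.csv(tmp)), 4)
})
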
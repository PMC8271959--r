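test_that("NIfTI round trip preserves voxels and spacing", {
  ph <- make_phantom(phantom_spec(seed = 3))
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$image, tmp)
  back <- read_volume(tmp)
  expect_equal(dim(back$voxels), c(64L, 64L, 16L))
  expect_equal(back$spacing, c(1, 1, 2.5))
  expect_equal(back$voxels, ph$image$voxels, tolerance = 1e-6)

  tmp2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$labels, tmp2)
  lab <- read_volume(tmp2, labels = TRUE, num_classes = 5)
  expect_identical(lab$labels, ph$labels$labels)
  expect_equal(lab$num_classes, 5L)
})

test_that("read_volume rejects missing files and non-3D images", {
  expect_error(read_volume("no/such/file.nii.gz"), "not found")
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 8, 8)), tmp)
  expect_error(read_volume(tmp), "3D")
})

test_that("HU windowing matches the truncated linear rescaling", {
  w1 <- window_spec(-1000, 400)
  expect_equal(normalize_hu(array(400, c(1, 1, 1)), w1)[1], 1.0)
  expect_equal(normalize_hu(array(-1200, c(1, 1, 1)), w1)[1], 0.0)
  w2 <- window_spec(-400, 400)
  expect_equal(normalize_hu(array(-400, c(1, 1, 1)), w2)[1], 0.0)
  expect_equal(normalize_hu(array(0, c(1, 1, 1)), w2)[1], 0.5)
  # any finite input lands in [0,1]; monotone in the input
  x <- array(runif(200, -3000, 3000), c(10, 10, 2))
  y <- normalize_hu(x, w2)
  expect_true(all(y >= 0 & y <= 1))
  ord <- order(as.vector(x))
  expect_true(all(diff(as.vector(y)[ord]) >= 0))
  # idempotent on already-windowed data under the unit window
  expect_equal(normalize_hu(y, window_spec(0, 1)), y)
  expect_error(window_spec(400, -400), "exceed")
})

test_that("slice extraction is an inverse of restacking", {
  ph <- make_phantom(phantom_spec(seed = 5))
  vol <- normalize_hu(ph$image, default_window("segthor"))
  slices <- extract_slices(vol, ph$labels, patient_id = "p1")
  expect_length(slices, 16L)
  expect_equal(slices[[7]]$slice_index, 7L)
  expect_true(all(vapply(slices, function(s) all(dim(s$image) == c(64, 64)), logical(1))))
  back <- restack_labels(slices, spacing = ph$labels$spacing, num_classes = 5)
  expect_identical(back$labels, ph$labels$labels)
  # shape mismatch is an error
  bad <- ph$labels
  bad$labels <- bad$labels[1:32, , ]
  expect_error(extract_slices(vol, bad), "shapes differ")
  # a different axial axis slices along that axis
  s1 <- extract_slices(vol, ph$labels, axial_axis = 1)
  expect_length(s1, 64L)
  expect_equal(dim(s1[[1]]$image), c(64L, 16L))
  expect_equal(s1[[5]]$label, ph$labels$labels[5, , ])
})

test_that("model input replicates the gray channel three times", {
  img <- matrix(runif(64 * 48), 64, 48)
  x <- to_model_input(img)
  expect_equal(dim(x), c(3L, 64L, 48L))
  expect_equal(x[1, , ], x[3, , ])
  expect_equal(x[2, , ], img)
  expect_equal(max(x), max(img))
})
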
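# NIfTI volume I/O, Hounsfield-unit windowing and slice extraction.
#
# A CT volume is stored as a 3D array of HU values together with the voxel
# spacing in mm and the (uninterpreted) 4x4 affine from the file header.
# The axial axis is taken to be the last array axis by default; slices are
# therefore `voxels[, , k]`.

#' CT and label volume containers
#'
#' `ct_volume()` wraps a 3D array of Hounsfield-unit values with its voxel
#' spacing (mm per axis) and affine. `label_volume()` wraps an integer class
#' array in `[0, P-1]` with matching geometry; `P = 5` for the four-organ
#' (SegTHOR-style) configuration and `P = 7` for the six-organ
#' (StructSeg-style) configuration.
#'
#' @param voxels 3D numeric array of finite HU values.
#' @param spacing numeric length-3, mm per axis, all positive.
#' @param affine 4x4 matrix carried through I/O (not interpreted).
#' @return a `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), affine = diag(4)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("ct_volume: voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop("ct_volume: voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("ct_volume: spacing must be 3 positive values")
  structure(list(voxels = voxels, spacing = spacing, affine = affine),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @param labels 3D array of integers in `[0, num_classes - 1]`.
#' @param num_classes class count P (background included).
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), affine = diag(4),
                         num_classes = max(labels) + 1L) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("label_volume: labels must be a 3D array")
  if (any(labels != round(labels)) || any(labels < 0))
    stop("label_volume: labels must be non-negative integers")
  num_classes <- as.integer(num_classes)
  if (any(labels > num_classes - 1L))
    stop("label_volume: labels must lie in [0, num_classes-1]")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing), affine = affine,
                 num_classes = num_classes),
            class = "label_volume")
}

#' Read a NIfTI volume
#'
#' @param path a readable `.nii` / `.nii.gz` file.
#' @param labels logical; read as a [label_volume()] instead of [ct_volume()].
#' @param num_classes forwarded to [label_volume()] when `labels = TRUE`.
#' @return a [ct_volume()] or [label_volume()].
#' @export
read_volume <- function(path, labels = FALSE, num_classes = NULL) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("read_volume: expected a 3D image, got ", length(dim(img)), "D")
  arr <- array(as.vector(img), dim = dim(img))  # strip NIfTI attributes
  spacing <- abs(RNifti::pixdim(img))[1:3]
  affine <- tryCatch(unclass(RNifti::xform(img)), error = function(e) diag(4))
  if (labels) {
    if (is.null(num_classes)) num_classes <- max(arr) + 1L
    label_volume(arr, spacing, affine, num_classes)
  } else {
    ct_volume(arr, spacing, affine)
  }
}

#' Write a volume to NIfTI
#'
#' Label volumes are written as unsigned integer data with the source affine.
#'
#' @param volume a [ct_volume()] or [label_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "label_volume")) {
    arr <- volume$labels
    datatype <- "uint8"
    if (volume$num_classes > 255L) datatype <- "int32"
  } else if (inherits(volume, "ct_volume")) {
    arr <- volume$voxels
    datatype <- "float"
  } else stop("write_volume: need a ct_volume or label_volume")
  img <- RNifti::asNifti(structure(arr, pixdim = volume$spacing),
                         datatype = datatype)
  if (is.matrix(volume$affine) && !isTRUE(all.equal(volume$affine, diag(4))))
    RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Hounsfield window specification
#'
#' @param lower,upper window bounds A < B in HU.
#' @return a `window_spec` object.
#' @export
window_spec <- function(lower, upper) {
  if (!(upper > lower)) stop("window_spec: upper bound must exceed lower bound")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "window_spec")
}

#' Default HU windows per dataset configuration
#'
#' `(-1000, 400)` for the six-organ (StructSeg-style) configuration and
#' `(-400, 400)` for the four-organ (SegTHOR-style) configuration.
#'
#' @param config `"segthor"` or `"structseg"`.
#' @return a [window_spec()].
#' @export
default_window <- function(config = c("segthor", "structseg")) {
  config <- match.arg(config)
  switch(config,
         segthor = window_spec(-400, 400),
         structseg = window_spec(-1000, 400))
}

#' Normalise HU values into the unit interval
#'
#' Applies `clip((I - A) / (B - A), 0, 1)` elementwise: values are windowed
#' to `[A, B]` (truncating irrelevant intensities) and rescaled to `[0, 1]`.
#'
#' @param volume a [ct_volume()] or plain numeric array.
#' @param window a [window_spec()].
#' @return object of the same kind as `volume`, with values in `[0, 1]`.
#' @export
normalize_hu <- function(volume, window) {
  stopifnot(inherits(window, "window_spec"))
  arr <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  out <- (arr - window$lower) / (window$upper - window$lower)
  out <- pmin(pmax(out, 0), 1)
  if (inherits(volume, "ct_volume")) {
    volume$voxels <- array(out, dim = dim(arr))
    volume
  } else {
    array(out, dim = dim(arr) %||% length(out))
  }
}

#' Extract axial 2D slices from a normalised volume
#'
#' Produces one image/label slice pair per axial index (last axis), order
#' preserved, so restacking the label slices reconstructs the label volume.
#'
#' @param volume a normalised [ct_volume()] (values in `[0,1]`).
#' @param labels the paired [label_volume()].
#' @param patient_id identifier recorded in each pair.
#' @param keep_empty keep slices whose label plane is all background
#'   (default TRUE).
#' @param axial_axis which array axis is axial (slices are taken along it);
#'   the last axis by default.
#' @return list of `slice_pair` objects with fields `image`, `label`,
#'   `patient_id`, `slice_index`.
#' @export
extract_slices <- function(volume, labels, patient_id = "unknown",
                           keep_empty = TRUE, axial_axis = 3L) {
  img <- volume$voxels
  lab <- labels$labels
  if (!all(dim(img) == dim(lab)))
    stop("extract_slices: image and label shapes differ")
  if (!axial_axis %in% 1:3) stop("extract_slices: axial_axis must be 1, 2 or 3")
  if (axial_axis != 3L) {
    perm <- c(setdiff(1:3, axial_axis), axial_axis)
    img <- aperm(img, perm)
    lab <- aperm(lab, perm)
  }
  n <- dim(img)[3]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    out[[k]] <- structure(list(image = img[, , k], label = lab[, , k],
                               patient_id = patient_id, slice_index = k),
                          class = "slice_pair")
  }
  if (!keep_empty) out <- Filter(function(s) any(s$label > 0L), out)
  out
}

#' Convert a slice to the 3-channel model input
#'
#' Replicates the single normalised gray channel three times to match the
#' 3-channel stem of ImageNet-style backbones.
#'
#' @param slice a `slice_pair` (or plain H x W matrix).
#' @return numeric array `c(3, H, W)` with identical channels.
#' @export
to_model_input <- function(slice) {
  img <- if (inherits(slice, "slice_pair")) slice$image else slice
  d <- dim(img)
  aperm(array(img, dim = c(d[1], d[2], 3L)), c(3L, 1L, 2L))
}

#' Restack label slices into a label volume
#'
#' Inverse of [extract_slices()] for the label planes.
#'
#' @param slices list of `slice_pair` objects (all slices, in order).
#' @param spacing,affine geometry of the reconstructed volume.
#' @param num_classes class count P.
#' @return a [label_volume()].
#' @export
restack_labels <- function(slices, spacing = c(1, 1, 1), affine = diag(4),
                           num_classes = NULL) {
  d2 <- dim(slices[[1]]$label)
  arr <- array(0L, dim = c(d2, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$label
  if (is.null(num_classes)) num_classes <- max(arr) + 1L
  label_volume(arr, spacing, affine, num_classes)
}
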
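# Deterministic phantom CT generator.
#
# The default phantom mimics the four-organ thoracic task at toy scale:
# inside a noisy soft-tissue background it renders a thin low-contrast tube
# (esophagus analog: small, ambiguous boundary, barely above background), a
# large bright ellipsoid (heart analog), an air-filled tube (trachea analog)
# and a bright tube (aorta analog). Labels are exactly the rendered
# primitives; everything is fully determined by the seed.

#' Phantom specification
#'
#' @param shape integer length-3 grid size (last axis = axial).
#' @param spacing mm per axis.
#' @param organs list of organ descriptors; each a list with fields
#'   `class` (integer in `[1, P-1]`), `primitive` (`"tube"` along the axial
#'   axis or `"ellipsoid"`), `center` (x, y, z voxel coordinates; tube uses
#'   x, y), `radius` (tube) or `axes` (ellipsoid semi-axes, voxels),
#'   `mean_hu`, and optionally `wobble` (tube centreline sinusoidal
#'   amplitude, voxels).
#' @param background_hu mean background intensity (soft tissue, HU).
#' @param noise_sd Gaussian noise standard deviation (HU).
#' @param num_classes class count P (background = 0).
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 16L), spacing = c(1, 1, 2.5),
                         organs = default_phantom_organs(),
                         background_hu = 30, noise_sd = 10,
                         num_classes = 5L, seed = 1L) {
  ids <- vapply(organs, function(o) as.integer(o$class), integer(1))
  if (anyDuplicated(ids)) stop("phantom_spec: organ class ids must be distinct")
  if (any(ids < 1L) || any(ids > num_classes - 1L))
    stop("phantom_spec: organ classes must lie in [1, P-1]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 organs = organs, background_hu = background_hu,
                 noise_sd = noise_sd, num_classes = as.integer(num_classes),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param shape grid the organs must fit into.
#' @export
default_phantom_organs <- function(shape = c(64L, 64L, 16L)) {
  cx <- shape[1] / 2; cy <- shape[2] / 2
  list(
    # esophagus analog: thin tube, contrast only +30 HU over background
    list(class = 1L, primitive = "tube", center = c(cx + 8, cy + 6),
         radius = 2.5, mean_hu = 60, wobble = 2),
    # heart analog: large bright ellipsoid
    list(class = 2L, primitive = "ellipsoid", center = c(cx - 10, cy - 8, shape[3] / 2),
         axes = c(11, 9, shape[3] * 0.45), mean_hu = 120),
    # trachea analog: air tube
    list(class = 3L, primitive = "tube", center = c(cx + 4, cy - 20),
         radius = 3, mean_hu = -950, wobble = 1),
    # aorta analog: bright contrast-filled tube
    list(class = 4L, primitive = "tube", center = c(cx + 18, cy - 6),
         radius = 4, mean_hu = 200, wobble = 1)
  )
}

render_organ_mask <- function(organ, shape) {
  xs <- seq_len(shape[1]); ys <- seq_len(shape[2]); zs <- seq_len(shape[3])
  mask <- array(FALSE, dim = shape)
  if (organ$primitive == "tube") {
    wob <- organ$wobble %||% 0
    for (k in zs) {
      ph <- 2 * pi * (k - 1) / shape[3]
      cx <- organ$center[1] + wob * sin(ph)
      cy <- organ$center[2] + wob * cos(ph)
      d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
      mask[, , k] <- d2 <= organ$radius^2
    }
  } else if (organ$primitive == "ellipsoid") {
    c3 <- organ$center; ax <- organ$axes
    for (k in zs) {
      zz <- ((k - c3[3]) / ax[3])^2
      if (zz > 1) next
      d2 <- outer(((xs - c3[1]) / ax[1])^2, ((ys - c3[2]) / ax[2])^2, `+`)
      mask[, , k] <- d2 + zz <= 1
    }
  } else stop("unknown primitive: ", organ$primitive)
  mask
}

#' Generate a phantom CT volume with ground-truth labels
#'
#' Background voxels are drawn as Gaussian noise around `background_hu`;
#' each organ is rendered at its mean HU (same noise). When organs overlap,
#' the later class wins and a warning is issued. Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([ct_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  shape <- spec$shape
  hu <- array(spec$background_hu, dim = shape)
  lab <- array(0L, dim = shape)
  overlap <- FALSE
  for (organ in spec$organs) {
    m <- render_organ_mask(organ, shape)
    if (any(lab[m] != 0L)) overlap <- TRUE
    hu[m] <- organ$mean_hu
    lab[m] <- as.integer(organ$class)
  }
  if (overlap) warning("make_phantom: overlapping organs; later class wins")
  if (spec$noise_sd > 0)
    hu <- hu + array(stats::rnorm(prod(shape), sd = spec$noise_sd), dim = shape)
  list(image = ct_volume(hu, spec$spacing),
       labels = label_volume(lab, spec$spacing, num_classes = spec$num_classes))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulated rater specification
#'
#' @param p sensitivities, one per rater, in (0.5, 1].
#' @param q specificities, one per rater, in (0.5, 1].
#' @param seed RNG seed.
#' @return a `rater_spec` object.
#' @export
rater_spec <- function(p, q, seed = 1L) {
  if (length(p) != length(q)) stop("rater_spec: p and q lengths differ")
  if (length(p) < 2L) stop("rater_spec: need at least 2 raters")
  if (any(p <= 0.5) || any(p > 1) || any(q <= 0.5) || any(q > 1))
    stop("rater_spec: p and q must lie in (0.5, 1]")
  structure(list(p = as.numeric(p), q = as.numeric(q), seed = as.integer(seed)),
            class = "rater_spec")
}

#' Simulate rater decisions from a known ground truth
#'
#' Realises the generative model STAPLE assumes: independently per voxel,
#' rater j marks a true-foreground voxel with probability `p[j]` and a
#' true-background voxel with probability `1 - q[j]`.
#'
#' @param gt ground truth, a [binary_mask()] or logical array with some
#'   foreground and some background.
#' @param raters a [rater_spec()].
#' @return a [rater_stack()] over the full voxel grid.
#' @export
simulate_raters <- function(gt, raters) {
  stopifnot(inherits(raters, "rater_spec"))
  g <- if (inherits(gt, "binary_mask")) gt$mask else as.array(gt)
  gv <- as.numeric(as.vector(g) > 0)
  if (all(gv == 1) || all(gv == 0))
    stop("simulate_raters: ground truth must contain foreground and background")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(raters$seed)
  V <- length(gv)
  R <- length(raters$p)
  D <- matrix(0, nrow = R, ncol = V)
  for (j in seq_len(R)) {
    prob <- ifelse(gv == 1, raters$p[j], 1 - raters$q[j])
    D[j, ] <- as.numeric(stats::runif(V) < prob)
  }
  rater_stack(D, dim = dim(g))
}

#' Phantom specification with per-patient anatomical variation
#'
#' Jitters every organ centre by a few voxels (uniform in +/- 2) and organ
#' sizes by +/- 15 percent, deterministically from the seed, so that a
#' multi-patient dataset does not repeat one fixed geometry.
#'
#' @param seed integer seed controlling both the jitter and the noise.
#' @param shape,spacing forwarded to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, shape = c(64L, 64L, 16L),
                                spacing = c(1, 1, 2.5)) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed + 1000003L)
  organs <- lapply(default_phantom_organs(shape), function(o) {
    o$center[1:2] <- o$center[1:2] + stats::runif(2, -2, 2)
    scale <- stats::runif(1, 0.85, 1.15)
    if (o$primitive == "tube") o$radius <- o$radius * scale
    else o$axes[1:2] <- o$axes[1:2] * scale
    o
  })
  phantom_spec(shape = shape, spacing = spacing, organs = organs, seed = seed)
}

#' Write a phantom dataset of several patients
#'
#' Writes `ct_<id>.nii.gz` / `lab_<id>.nii.gz` pairs, one per patient, each
#' generated with seed `seed + patient index`.
#'
#' @param dir output directory (created if needed).
#' @param n_patients number of volumes.
#' @param seed base seed.
#' @param spec_fn function(seed) returning the [phantom_spec()] per patient.
#' @return data.frame with columns patient_id, image, labels.
#' @export
write_phantom_dataset <- function(dir, n_patients = 8L, seed = 17L,
                                  spec_fn = random_phantom_spec) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_patients), function(i) {
    ph <- make_phantom(spec_fn(seed + i))
    id <- sprintf("patient%02d", i)
    fimg <- file.path(dir, paste0("ct_", id, ".nii.gz"))
    flab <- file.path(dir, paste0("lab_", id, ".nii.gz"))
    write_volume(ph$image, fimg)
    write_volume(ph$labels, flab)
    data.frame(patient_id = id, image = fimg, labels = flab)
  })
  do.call(rbind, rows)
}
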
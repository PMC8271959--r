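# Evaluation metrics: volumetric Dice overlap and (percentile) Hausdorff
# distance between mask surfaces, in millimetres. Surfaces are the
# face-connected boundary voxels (6-connectivity in 3D, 4 in 2D; the grid
# border counts as background) with voxel centres scaled by the spacing, so
# anisotropic voxels are respected.

#' Spacing-aware binary mask
#'
#' @param mask logical (or 0/1) 2D or 3D array.
#' @param spacing mm per axis, positive, one entry per array axis.
#' @return a `binary_mask` object.
#' @export
binary_mask <- function(mask, spacing = rep(1, length(dim(mask)))) {
  mask <- as.array(mask)
  nd <- length(dim(mask))
  if (!nd %in% c(2L, 3L)) stop("binary_mask: mask must be 2D or 3D")
  if (length(spacing) != nd || any(spacing <= 0))
    stop("binary_mask: spacing must be positive, one value per axis")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

as_binary_mask <- function(x, spacing = NULL) {
  if (inherits(x, "binary_mask")) return(x)
  binary_mask(x, spacing %||% rep(1, length(dim(as.array(x)))))
}

#' Dice similarity coefficient
#'
#' `2|T intersect N| / (|T| + |N|)`. Two empty masks score 1; exactly one
#' empty mask scores 0.
#'
#' @param t,n [binary_mask()]s (or plain logical arrays) of identical shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(t, n) {
  t <- as_binary_mask(t); n <- as_binary_mask(n)
  if (!all(dim(t$mask) == dim(n$mask))) stop("dice_score: shape mismatch")
  st <- sum(t$mask); sn <- sum(n$mask)
  if (st + sn == 0) return(1)
  2 * sum(t$mask & n$mask) / (st + sn)
}

#' Extract the surface voxels of a mask
#'
#' A foreground voxel belongs to the surface if at least one face-adjacent
#' neighbour is background or lies outside the grid. Coordinates are voxel
#' indices scaled by the spacing (mm).
#'
#' @param mask a [binary_mask()] (or logical array), non-empty.
#' @return matrix of surface point coordinates in mm (one row per voxel).
#' @export
extract_surface <- function(mask) {
  m <- as_binary_mask(mask)
  a <- m$mask
  if (!any(a)) stop("extract_surface: mask is empty")
  nd <- length(dim(a))
  d <- dim(a)
  border <- array(FALSE, dim = d)
  if (nd == 2L) {
    nb <- array(TRUE, d); nb[-d[1], ] <- !a[-1, ]; border <- border | nb
    nb <- array(TRUE, d); nb[-1, ] <- !a[-d[1], ]; border <- border | nb
    nb <- array(TRUE, d); nb[, -d[2]] <- !a[, -1]; border <- border | nb
    nb <- array(TRUE, d); nb[, -1] <- !a[, -d[2]]; border <- border | nb
  } else {
    nb <- array(TRUE, d); nb[-d[1], , ] <- !a[-1, , ]; border <- border | nb
    nb <- array(TRUE, d); nb[-1, , ] <- !a[-d[1], , ]; border <- border | nb
    nb <- array(TRUE, d); nb[, -d[2], ] <- !a[, -1, ]; border <- border | nb
    nb <- array(TRUE, d); nb[, -1, ] <- !a[, -d[2], ]; border <- border | nb
    nb <- array(TRUE, d); nb[, , -d[3]] <- !a[, , -1]; border <- border | nb
    nb <- array(TRUE, d); nb[, , -1] <- !a[, , -d[3]]; border <- border | nb
  }
  surf <- a & border
  idx <- which(surf, arr.ind = TRUE)
  sweep(idx, 2L, m$spacing, "*")
}

#' Hausdorff distance between mask surfaces (mm)
#'
#' With `percentile = 100`, the classic symmetric Hausdorff distance
#' `max(sup_x inf_y d(x,y), sup_y inf_x d(x,y))` between the two surface
#' point sets. With a smaller percentile (typically 95), that percentile of
#' each directed distance sample is taken before the outer max, which
#' suppresses outlier boundary points.
#'
#' @param t,n non-empty [binary_mask()]s of identical shape and spacing.
#' @param percentile value in `(0, 100]`.
#' @return distance in mm, or `NA_real_` if either mask is empty.
#' @export
hausdorff <- function(t, n, percentile = 100) {
  t <- as_binary_mask(t); n <- as_binary_mask(n)
  if (!all(dim(t$mask) == dim(n$mask))) stop("hausdorff: shape mismatch")
  if (percentile <= 0 || percentile > 100) stop("hausdorff: percentile in (0,100]")
  if (!any(t$mask) || !any(n$mask)) return(NA_real_)
  st <- extract_surface(t)
  sn <- extract_surface(n)
  d_tn <- .min_dist_rows(st, sn)
  d_nt <- .min_dist_rows(sn, st)
  if (percentile == 100) {
    max(max(d_tn), max(d_nt))
  } else {
    max(stats::quantile(d_tn, percentile / 100, names = FALSE),
        stats::quantile(d_nt, percentile / 100, names = FALSE))
  }
}

#' @rdname hausdorff
#' @export
hd95 <- function(t, n) hausdorff(t, n, percentile = 95)

#' Per-class segmentation metrics table
#'
#' Computes Dice, HD and HD95 for every foreground class of the ground
#' truth. Classes with an empty prediction get Dice 0 and missing (NA)
#' surface distances.
#'
#' @param pred,gt [label_volume()]s of identical shape.
#' @param classes integer classes to evaluate; default all foreground
#'   classes present in `gt`.
#' @param patient_id identifier copied into the output rows.
#' @return data.frame with columns patient_id, class, dice, hd, hd95.
#' @export
evaluate_segmentation <- function(pred, gt, classes = NULL, patient_id = "unknown") {
  if (!all(dim(pred$labels) == dim(gt$labels)))
    stop("evaluate_segmentation: shape mismatch")
  if (is.null(classes)) {
    classes <- sort(unique(as.vector(gt$labels)))
    classes <- classes[classes > 0L]
  }
  sp <- gt$spacing
  rows <- lapply(classes, function(cl) {
    p <- binary_mask(pred$labels == cl, sp)
    g <- binary_mask(gt$labels == cl, sp)
    data.frame(patient_id = patient_id, class = cl,
               dice = dice_score(p, g),
               hd = hausdorff(p, g, 100),
               hd95 = hausdorff(p, g, 95))
  })
  do.call(rbind, rows)
}
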
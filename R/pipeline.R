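# K-fold training, slice-wise inference, fold fusion and evaluation.
#
# Training follows the published recipe: slices of windowed volumes, the
# combined Dice + weighted cross-entropy loss, Adam, horizontal-flip /
# rotation / elastic augmentation, and a patient-level K-fold split whose
# fold models are fused by STAPLE at inference time.

#' Training configuration
#'
#' @param data data.frame with columns `patient_id`, `image`, `labels`
#'   (NIfTI paths), e.g. from [write_phantom_dataset()].
#' @param backbone a [backbone_spec()].
#' @param num_classes class count P.
#' @param window a [window_spec()].
#' @param loss a [loss_weights()].
#' @param folds number of folds K (>= 2; published setups: 5 and 4).
#' @param epochs training epochs (published setup: 30).
#' @param lr Adam learning rate.
#' @param batch_size slices per optimisation step.
#' @param augment list with `hflip` (probability), `rotate` (max degrees),
#'   `elastic` (list `alpha` displacement px, `grid` coarse knots; `NULL`
#'   disables).
#' @param norm a [norm_spec()].
#' @param keep_empty keep slices without foreground during training.
#' @param seed master seed.
#' @return a `train_config` object.
#' @export
train_config <- function(data, backbone = backbone_spec("resnet34"),
                         num_classes = 5L, window = default_window("segthor"),
                         loss = default_loss_weights("segthor"),
                         folds = 4L, epochs = 30L, lr = 3e-4, batch_size = 8L,
                         augment = list(hflip = 0.5, rotate = 15,
                                        elastic = list(alpha = 4, grid = 4L)),
                         norm = norm_spec("group"), keep_empty = TRUE,
                         seed = 1L) {
  if (folds < 2L) stop("train_config: folds must be >= 2")
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  if (length(loss$phi) != num_classes)
    stop("train_config: loss phi length must equal num_classes")
  structure(list(data = data, backbone = backbone,
                 num_classes = as.integer(num_classes), window = window,
                 loss = loss, folds = as.integer(folds),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), augment = augment,
                 norm = norm, keep_empty = isTRUE(keep_empty),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Patient-level K-fold assignment
#'
#' Shuffles the patients with the given seed and deals them round-robin, so
#' fold sizes differ by at most one and no patient appears in two folds.
#' Splitting is always by patient, never by slice.
#'
#' @param patients character vector of patient ids.
#' @param k number of folds (<= number of patients).
#' @param seed RNG seed.
#' @return named integer vector mapping patient id to fold (1..k).
#' @export
kfold_split <- function(patients, k, seed = 1L) {
  patients <- as.character(patients)
  if (k > length(patients)) stop("kfold_split: k exceeds number of patients")
  if (anyDuplicated(patients)) stop("kfold_split: duplicated patient ids")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  shuffled <- sample(patients)
  folds <- rep(seq_len(k), length.out = length(patients))
  stats::setNames(folds[match(patients, shuffled)], patients)
}

# --- augmentation ----------------------------------------------------------

bilinear_grid_upsample <- function(g, H, W) {
  m <- nrow(g); n <- ncol(g)
  ri <- seq(1, m, length.out = H)
  ci <- seq(1, n, length.out = W)
  r0 <- pmin(floor(ri), m - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), n - 1L); fc <- ci - c0
  a <- g[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    g[r0 + 1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    g[r0, c0 + 1, drop = FALSE] * outer(1 - fr, fc) +
    g[r0 + 1, c0 + 1, drop = FALSE] * outer(fr, fc)
  a
}

# Random flip / rotation / elastic warp of one image+label slice pair.
# Uses the current RNG stream; labels warped with nearest neighbour.
augment_slice <- function(image, label, aug) {
  H <- nrow(image); W <- ncol(image)
  if (!is.null(aug$hflip) && stats::runif(1) < aug$hflip) {
    image <- image[, W:1]
    label <- label[, W:1]
  }
  base_r <- matrix(seq_len(H), H, W)
  base_c <- matrix(seq_len(W), H, W, byrow = TRUE)
  srcr <- base_r; srcc <- base_c
  warped <- FALSE
  if (!is.null(aug$rotate) && aug$rotate > 0) {
    th <- stats::runif(1, -aug$rotate, aug$rotate) * pi / 180
    cr <- (H + 1) / 2; cc <- (W + 1) / 2
    dr <- base_r - cr; dc <- base_c - cc
    srcr <- cr + cos(th) * dr - sin(th) * dc
    srcc <- cc + sin(th) * dr + cos(th) * dc
    warped <- TRUE
  }
  if (!is.null(aug$elastic)) {
    gsz <- aug$elastic$grid %||% 4L
    alpha <- aug$elastic$alpha %||% 4
    gr <- matrix(stats::rnorm((gsz + 1)^2, sd = alpha), gsz + 1)
    gc <- matrix(stats::rnorm((gsz + 1)^2, sd = alpha), gsz + 1)
    srcr <- srcr + bilinear_grid_upsample(gr, H, W)
    srcc <- srcc + bilinear_grid_upsample(gc, H, W)
    warped <- TRUE
  }
  if (warped) {
    image <- .warp2d(image, srcr, srcc, FALSE)
    label <- .warp2d(matrix(as.numeric(label), H, W), srcr, srcc, TRUE)
    storage.mode(label) <- "integer"
  }
  list(image = image, label = label)
}

# --- dataset loading -------------------------------------------------------

load_slice_dataset <- function(data, window, num_classes, keep_empty = TRUE) {
  out <- list()
  for (i in seq_len(nrow(data))) {
    vol <- read_volume(data$image[i])
    lab <- read_volume(data$labels[i], labels = TRUE, num_classes = num_classes)
    vol <- normalize_hu(vol, window)
    out[[data$patient_id[i]]] <-
      extract_slices(vol, lab, data$patient_id[i], keep_empty = keep_empty)
  }
  out
}

make_batch <- function(slices) {
  H <- nrow(slices[[1]]$image); W <- ncol(slices[[1]]$image)
  N <- length(slices)
  x <- array(0, dim = c(3L, H, W, N))
  y <- array(0L, dim = c(H, W, N))
  for (i in seq_len(N)) {
    x[, , , i] <- to_model_input(slices[[i]]$image)
    y[, , i] <- slices[[i]]$label
  }
  list(x = x, y = y)
}

# mean foreground 2D Dice over the slices of one patient set (argmax masks)
slicewise_val_dice <- function(net, patient_slices, num_classes, batch_size = 8L) {
  scores <- c()
  for (slices in patient_slices) {
    idx <- seq_along(slices)
    for (b in split(idx, ceiling(idx / batch_size))) {
      batch <- make_batch(slices[b])
      probs <- network_forward(net, batch$x, train = FALSE)
      P <- dim(probs)[1]
      pm <- matrix(probs, nrow = P)
      pred <- array(max.col(t(pm), ties.method = "first") - 1L, dim = dim(batch$y))
      for (i in seq_along(b)) {
        cls <- unique(as.vector(batch$y[, , i]))
        cls <- cls[cls > 0L]
        if (length(cls) == 0L) next
        ds <- vapply(cls, function(cl)
          dice_score(pred[, , i] == cl, batch$y[, , i] == cl), numeric(1))
        scores <- c(scores, mean(ds))
      }
    }
  }
  if (length(scores) == 0L) return(NA_real_)
  mean(scores)
}

#' Train one fold
#'
#' Trains the network on every patient outside `fold` with the combined
#' loss and Adam, validates slice-wise after each epoch on the held-out
#' fold, and saves the checkpoint with the best mean foreground validation
#' Dice. The per-epoch log is stored inside the checkpoint and returned.
#'
#' @param cfg a [train_config()].
#' @param assignment a [kfold_split()] of the patients in `cfg$data`.
#' @param fold fold index to hold out.
#' @param checkpoint_path where to save the best checkpoint (`.rds`).
#' @param verbose print per-epoch progress.
#' @return invisibly, a list with `checkpoint` (path) and `log` (data.frame
#'   epoch / train_loss / val_dice).
#' @export
train_fold <- function(cfg, assignment, fold, checkpoint_path,
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  train_ids <- names(assignment)[assignment != fold]
  val_ids <- names(assignment)[assignment == fold]
  if (length(train_ids) == 0L) stop("train_fold: empty training set")
  if (length(intersect(train_ids, val_ids)) > 0L)
    stop("train_fold: fold assignment is not a partition")
  dat <- cfg$data[cfg$data$patient_id %in% c(train_ids, val_ids), ]
  slices <- load_slice_dataset(dat, cfg$window, cfg$num_classes, cfg$keep_empty)
  train_slices <- do.call(c, unname(slices[train_ids]))
  val_slices <- slices[val_ids]

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed * 1000L + fold)
  net <- build_network(cfg$backbone, cfg$num_classes, cfg$norm)
  opt <- adam_optimizer(net, lr = cfg$lr)
  best_dice <- -Inf
  log <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(train_slices))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      sl <- train_slices[b]
      if (!is.null(cfg$augment))
        sl <- lapply(sl, function(s) {
          a <- augment_slice(s$image, s$label, cfg$augment)
          s$image <- a$image; s$label <- a$label; s
        })
      batch <- make_batch(sl)
      logits <- forward_logits(net, batch$x, train = TRUE)
      lg <- combined_loss_grad(logits, batch$y, cfg$loss)
      backward_logits(net, lg$grad)
      adam_step(opt)
      epoch_loss <- epoch_loss + lg$loss * length(b)
    }
    epoch_loss <- epoch_loss / length(train_slices)
    vd <- slicewise_val_dice(net, val_slices, cfg$num_classes, cfg$batch_size)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = epoch_loss,
                                 val_dice = vd))
    if (verbose)
      message(sprintf("fold %d epoch %d: loss %.4f val dice %.4f",
                      fold, epoch, epoch_loss, vd))
    if (is.na(vd)) vd <- -epoch_loss
    if (vd >= best_dice) {
      best_dice <- vd
      save_checkpoint(net, checkpoint_path, window = cfg$window,
                      extra = list(fold = fold, log = log, seed = cfg$seed))
    }
  }
  # refresh stored log so the final checkpoint carries the full history
  ck <- readRDS(checkpoint_path)
  ck$extra$log <- log
  saveRDS(ck, checkpoint_path)
  invisible(list(checkpoint = checkpoint_path, log = log))
}

#' Predict a label volume with one checkpoint
#'
#' Windows the volume with the checkpoint's stored window, runs every axial
#' slice through the network, argmaxes the class probabilities and restacks
#' the slices into a label volume of the input shape.
#'
#' @param checkpoint path to a saved checkpoint or the result of
#'   [load_checkpoint()].
#' @param volume a [ct_volume()].
#' @param batch_size slices per forward pass.
#' @return a [label_volume()].
#' @export
predict_volume <- function(checkpoint, volume, batch_size = 8L) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  net <- ck$net
  window <- ck$window %||% default_window("segthor")
  vol <- normalize_hu(volume, window)
  d <- dim(vol$voxels)
  pred <- array(0L, dim = d)
  idx <- seq_len(d[3])
  for (b in split(idx, ceiling(idx / batch_size))) {
    x <- array(0, dim = c(3L, d[1], d[2], length(b)))
    for (i in seq_along(b)) x[, , , i] <- to_model_input(vol$voxels[, , b[i]])
    probs <- network_forward(net, x, train = FALSE)
    P <- dim(probs)[1]
    cls <- max.col(t(matrix(probs, nrow = P)), ties.method = "first") - 1L
    pred[, , b] <- array(cls, dim = c(d[1], d[2], length(b)))
  }
  label_volume(pred, volume$spacing, volume$affine, net$num_classes)
}

#' Predict with every fold model and fuse by STAPLE
#'
#' Runs [predict_volume()] once per checkpoint and combines the resulting
#' label volumes with [fuse_multiclass()].
#'
#' @param checkpoints list (length >= 2) of checkpoint paths or loaded
#'   checkpoints.
#' @param volume a [ct_volume()].
#' @param cfg a [fusion_config()].
#' @param batch_size slices per forward pass.
#' @return the fused [label_volume()].
#' @export
run_fold_fusion <- function(checkpoints, volume, cfg = fusion_config(),
                            batch_size = 8L) {
  if (length(checkpoints) < 2L)
    stop("run_fold_fusion: need at least 2 checkpoints")
  preds <- lapply(checkpoints, predict_volume, volume = volume,
                  batch_size = batch_size)
  fuse_multiclass(preds, cfg)
}

#' Write a per-patient metrics table as CSV
#'
#' @param metrics data.frame from [evaluate_segmentation()] (possibly
#'   rbind-ed over patients).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
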
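# Training objective: L = theta * Dice_loss + sigma * weighted_CE.
#
# Dice_loss is 1 minus the mean per-class soft Dice computed from predicted
# probabilities against one-hot targets with smoothing eps; weighted_CE is
# the per-pixel cross-entropy weighted by a per-class factor phi. The
# published configuration uses theta = 0.9, sigma = 0.1, with phi
# (0.2, 0.5, 0.5, 0.5, 0.5) for the four-organ task (background, heart,
# esophagus, trachea, aorta) and (0.1, 0.2, 0.2, 0.3, 0.4, 0.4, 0.4) for the
# six-organ task.

#' Loss weight specification
#'
#' @param theta weight of the soft-Dice term (>= 0).
#' @param sigma weight of the cross-entropy term (>= 0).
#' @param phi positive per-class weights, length = number of classes.
#' @return a `loss_weights` object.
#' @export
loss_weights <- function(theta = 0.9, sigma = 0.1, phi) {
  if (theta < 0 || sigma < 0) stop("loss_weights: theta and sigma must be >= 0")
  if (any(phi <= 0)) stop("loss_weights: phi entries must be positive")
  structure(list(theta = theta, sigma = sigma, phi = as.numeric(phi)),
            class = "loss_weights")
}

#' Default loss weights per dataset configuration
#'
#' @param config `"segthor"` (P = 5) or `"structseg"` (P = 7).
#' @return a [loss_weights()] with theta 0.9, sigma 0.1 and the published phi.
#' @export
default_loss_weights <- function(config = c("segthor", "structseg")) {
  config <- match.arg(config)
  phi <- switch(config,
                segthor = c(0.2, 0.5, 0.5, 0.5, 0.5),
                structseg = c(0.1, 0.2, 0.2, 0.3, 0.4, 0.4, 0.4))
  loss_weights(0.9, 0.1, phi)
}

check_probs_target <- function(probs, target) {
  d <- dim(probs)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("probs must be a P x H x W (or P x H x W x N) array")
  tgt <- as.integer(round(target))
  if (any(tgt < 0L) || any(tgt > d[1] - 1L))
    stop("labels must lie in [0, P-1]")
  if (length(tgt) * d[1] != length(probs))
    stop("probs and target sizes do not match")
  tgt
}

# per-class sums of probs, one-hot targets and their product
dice_sums <- function(probs, tgt) {
  P <- dim(probs)[1]
  pm <- matrix(probs, nrow = P)
  npix <- ncol(pm)
  sum_p <- .rowSums(pm, P, npix)
  sum_t <- tabulate(tgt + 1L, nbins = P)
  lin <- (tgt + 1L) + P * (seq_len(npix) - 1L)
  inter <- numeric(P)
  agg <- tapply(pm[lin], tgt, sum)
  inter[as.integer(names(agg)) + 1L] <- agg
  list(sum_p = sum_p, sum_t = sum_t, inter = inter, npix = npix, lin = lin)
}

#' Multi-class soft Dice loss
#'
#' `1 - (1/P) * sum_i (2 * sum(p_i t_i) + eps) / (sum(p_i) + sum(t_i) + eps)`
#' over classes i, with one-hot targets t and predicted probabilities p.
#' Zero (up to eps) iff the prediction equals the one-hot target.
#'
#' @param probs probability array `c(P, H, W)` or `c(P, H, W, N)`.
#' @param target integer label array `c(H, W)` (or with batch axis),
#'   values in `[0, P-1]`.
#' @param eps smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(probs, target, eps = 1e-6) {
  tgt <- check_probs_target(probs, target)
  s <- dice_sums(probs, tgt)
  dice_i <- (2 * s$inter + eps) / (s$sum_p + s$sum_t + eps)
  1 - mean(dice_i)
}

#' Class-weighted cross-entropy loss
#'
#' Mean over pixels of `-phi[t(x)] * log(p_{t(x)}(x))`, with the log
#' argument floored at 1e-12.
#'
#' @inheritParams dice_loss
#' @param phi positive per-class weights, length P.
#' @return non-negative scalar.
#' @export
weighted_ce <- function(probs, target, phi = rep(1, dim(probs)[1])) {
  if (any(phi < 0)) stop("weighted_ce: phi must be non-negative")
  tgt <- check_probs_target(probs, target)
  P <- dim(probs)[1]
  if (length(phi) != P) stop("weighted_ce: phi must have one entry per class")
  pm <- matrix(probs, nrow = P)
  lin <- (tgt + 1L) + P * (seq_len(ncol(pm)) - 1L)
  p_true <- pmax(pm[lin], 1e-12)
  mean(-phi[tgt + 1L] * log(p_true))
}

#' Combined segmentation loss
#'
#' `theta * dice_loss + sigma * weighted_ce`.
#'
#' @inheritParams dice_loss
#' @param weights a [loss_weights()].
#' @return non-negative scalar.
#' @export
combined_loss <- function(probs, target, weights = default_loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  weights$theta * dice_loss(probs, target) +
    weights$sigma * weighted_ce(probs, target, weights$phi)
}

# Loss value and gradient w.r.t. the logits (pre-softmax), used by the
# training loop. Softmax jacobian folded in analytically.
combined_loss_grad <- function(logits, target, weights) {
  probs <- softmax_channels(logits)
  tgt <- check_probs_target(probs, target)
  P <- dim(probs)[1]
  pm <- matrix(probs, nrow = P)
  npix <- ncol(pm)
  s <- dice_sums(probs, tgt)
  eps <- 1e-6
  den <- s$sum_p + s$sum_t + eps
  dice_i <- (2 * s$inter + eps) / den
  dice_val <- 1 - mean(dice_i)
  # d(dice_loss)/d p_i(x) = -(1/P) * (2*t_i(x) - dice_i) / den_i
  dL_dp <- matrix(rep(dice_i / den / P, npix), nrow = P)
  dL_dp[s$lin] <- dL_dp[s$lin] - 2 / (den[tgt + 1L] * P)
  dL_dp <- dL_dp * weights$theta
  # CE term: d(mean -phi_t log p_t)/d z_k = phi_t * (p_k - 1{k=t}) / npix
  p_true <- pmax(pm[s$lin], 1e-12)
  ce_val <- mean(-weights$phi[tgt + 1L] * log(p_true))
  wpix <- weights$phi[tgt + 1L] / npix
  dz_ce <- sweep(pm, 2L, wpix, "*")
  dz_ce[s$lin] <- dz_ce[s$lin] - wpix
  # softmax backward for the dice part: dz = p * (dL_dp - sum_k dL_dp_k p_k)
  inner <- .colSums(dL_dp * pm, P, npix)
  dz <- pm * sweep(dL_dp, 2L, inner, "-") + weights$sigma * dz_ce
  dim(dz) <- dim(logits)
  list(loss = weights$theta * dice_val + weights$sigma * ce_val,
       dice = dice_val, ce = ce_val, grad = dz)
}
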
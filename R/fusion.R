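# STAPLE label fusion of k-fold predictions.
#
# STAPLE (simultaneous truth and performance level estimation) treats the R
# candidate segmentations of one structure as raters with unknown
# sensitivity p_j and specificity q_j, and estimates by EM both the
# per-voxel posterior probability W_i of the true segmentation and the
# rater performance parameters:
#   E-step: W_i = a_i / (a_i + b_i),
#     a_i = pi_i     * prod_j p_j^{D_ij} (1-p_j)^{1-D_ij}
#     b_i = (1-pi_i) * prod_j q_j^{1-D_ij} (1-q_j)^{D_ij}
#   M-step: p_j = sum_i W_i D_ij / sum_i W_i
#           q_j = sum_i (1-W_i)(1-D_ij) / sum_i (1-W_i)
# The observed-data log-likelihood sum_i log(a_i + b_i) never decreases.

#' Rater stack
#'
#' Binary decisions of R raters over the V voxels of one structure.
#'
#' @param decisions R x V matrix with entries in `{0, 1}` (or a list of R
#'   equally shaped binary arrays, which are flattened).
#' @param dim optional voxel-grid dim used to reshape fused outputs.
#' @return a `rater_stack` object.
#' @export
rater_stack <- function(decisions, dim = NULL) {
  if (is.list(decisions)) {
    if (is.null(dim)) dim <- base::dim(decisions[[1]])
    decisions <- do.call(rbind, lapply(decisions, function(a) as.numeric(as.vector(a))))
  }
  if (!is.matrix(decisions)) stop("rater_stack: decisions must be an R x V matrix")
  if (nrow(decisions) < 2L) stop("rater_stack: need at least 2 raters")
  if (!all(decisions %in% c(0, 1))) stop("rater_stack: decisions must be binary")
  structure(list(decisions = decisions, dim = dim), class = "rater_stack")
}

#' Fusion configuration
#'
#' @param prior `"global-vote"` (default: a single global foreground prior
#'   equal to the mean rater vote fraction, the classic formulation),
#'   `"vote-fraction"` (per-voxel mean rater vote clamped to `[0.01, 0.99]`;
#'   spatially adaptive but it re-uses the votes that already enter the
#'   E-step, which biases the performance estimates), or a fixed value in
#'   (0,1) applied globally.
#' @param init_pq initial sensitivity/specificity, in (0.5, 1).
#' @param tol convergence tolerance on the change of `sum(W)`.
#' @param max_iter maximum EM iterations.
#' @param threshold posterior cut used to binarize fused masks, in (0,1).
#' @return a `fusion_config` object.
#' @export
fusion_config <- function(prior = "global-vote", init_pq = 0.99999,
                          tol = 1e-6, max_iter = 100L, threshold = 0.5) {
  if (tol <= 0) stop("fusion_config: tol must be positive")
  if (threshold <= 0 || threshold >= 1) stop("fusion_config: threshold in (0,1)")
  if (init_pq <= 0.5 || init_pq > 1) stop("fusion_config: init_pq in (0.5, 1]")
  if (is.numeric(prior) && (prior <= 0 || prior >= 1))
    stop("fusion_config: fixed prior must lie in (0,1)")
  if (is.character(prior) && !prior %in% c("global-vote", "vote-fraction"))
    stop("fusion_config: unknown prior kind")
  structure(list(prior = prior, init_pq = init_pq, tol = tol,
                 max_iter = as.integer(max_iter), threshold = threshold),
            class = "fusion_config")
}

#' Binary STAPLE expectation-maximization
#'
#' Estimates the consensus probability field and per-rater sensitivity /
#' specificity from a stack of binary segmentations. If no rater marks any
#' voxel the trivial empty result is returned without running EM.
#'
#' @param stack a [rater_stack()].
#' @param cfg a [fusion_config()].
#' @return a `staple_result` list: `posterior` (length V), `sensitivity`
#'   and `specificity` (length R), `iterations`, `converged`,
#'   `log_likelihood` (trace, one entry per iteration), `fused` (binary
#'   vector at `cfg$threshold`).
#' @export
staple_binary <- function(stack, cfg = fusion_config()) {
  stopifnot(inherits(stack, "rater_stack"))
  D <- stack$decisions
  R <- nrow(D); V <- ncol(D)
  if (!any(D == 1)) {
    return(structure(list(posterior = numeric(V),
                          sensitivity = rep(cfg$init_pq, R),
                          specificity = rep(cfg$init_pq, R),
                          iterations = 0L, converged = TRUE,
                          log_likelihood = numeric(0),
                          fused = numeric(V), dim = stack$dim),
                     class = "staple_result"))
  }
  votes <- .colMeans(D, R, V)
  pri <- if (identical(cfg$prior, "global-vote")) {
    rep(min(max(mean(votes), 0.01), 0.99), V)
  } else if (identical(cfg$prior, "vote-fraction")) {
    pmin(pmax(votes, 0.01), 0.99)
  } else rep(as.numeric(cfg$prior), V)
  p <- rep(cfg$init_pq, R)
  q <- rep(cfg$init_pq, R)
  clamp <- function(x) pmin(pmax(x, 1e-7), 1 - 1e-7)
  W <- votes
  sumW_old <- sum(W)
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    p <- clamp(p); q <- clamp(q)
    # E-step in log space: crossprod over raters
    la <- log(pri) + crossprod(D, log(p)) + crossprod(1 - D, log(1 - p))
    lb <- log1p(-pri) + crossprod(1 - D, log(q)) + crossprod(D, log(1 - q))
    mx <- pmax(la, lb)
    a <- exp(la - mx); b <- exp(lb - mx)
    W <- as.vector(a / (a + b))
    ll <- c(ll, sum(mx + log(a + b)))
    # M-step
    sW <- sum(W); sNW <- V - sW
    p <- as.vector(D %*% W) / sW
    q <- as.vector((1 - D) %*% (1 - W)) / sNW
    if (abs(sum(W) - sumW_old) < cfg$tol) { converged <- TRUE; break }
    sumW_old <- sum(W)
  }
  structure(list(posterior = W, sensitivity = clamp(p), specificity = clamp(q),
                 iterations = it, converged = converged, log_likelihood = ll,
                 fused = as.numeric(W >= cfg$threshold), dim = stack$dim),
            class = "staple_result")
}

#' Majority-vote fusion baseline
#'
#' A voxel is foreground iff strictly more than half of the raters mark it;
#' ties go to background.
#'
#' @param stack a [rater_stack()].
#' @return binary vector (or array when the stack has a `dim`).
#' @export
majority_vote <- function(stack) {
  stopifnot(inherits(stack, "rater_stack"))
  D <- stack$decisions
  out <- as.numeric(colSums(D) > nrow(D) / 2)
  if (!is.null(stack$dim)) dim(out) <- stack$dim
  out
}

#' Multi-class STAPLE fusion of label volumes
#'
#' Decomposes each of the R multi-class label volumes into one binary mask
#' per foreground class, fuses each class with [staple_binary()], and
#' reassembles a single label volume: each voxel gets the class with the
#' highest posterior if that posterior reaches `cfg$threshold`, else
#' background.
#'
#' @param label_volumes list of R >= 2 [label_volume()]s, same shape and P.
#' @param cfg a [fusion_config()].
#' @return the fused [label_volume()].
#' @export
fuse_multiclass <- function(label_volumes, cfg = fusion_config()) {
  if (length(label_volumes) < 2L) stop("fuse_multiclass: need >= 2 volumes")
  d <- dim(label_volumes[[1]]$labels)
  P <- label_volumes[[1]]$num_classes
  for (lv in label_volumes) {
    if (!all(dim(lv$labels) == d)) stop("fuse_multiclass: shape mismatch")
    if (lv$num_classes != P) stop("fuse_multiclass: class count mismatch")
  }
  V <- prod(d)
  post <- matrix(0, nrow = P - 1L, ncol = V)
  for (cl in seq_len(P - 1L)) {
    Dm <- do.call(rbind, lapply(label_volumes,
                                function(lv) as.numeric(lv$labels == cl)))
    res <- staple_binary(rater_stack(Dm, dim = d), cfg)
    post[cl, ] <- res$posterior
  }
  best <- max.col(t(post), ties.method = "first")
  bestp <- post[cbind(best, seq_len(V))]
  lab <- ifelse(bestp >= cfg$threshold, best, 0L)
  dim(lab) <- d
  label_volume(lab, label_volumes[[1]]$spacing, label_volumes[[1]]$affine, P)
}
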
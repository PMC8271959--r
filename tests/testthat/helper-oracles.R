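# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as plain loops, sharing no code with the
# package internals.

# surface voxels by explicit neighbour enumeration (6-/4-connectivity)
oracle_surface <- function(mask, spacing) {
  d <- dim(mask)
  nd <- length(d)
  pts <- NULL
  offs <- if (nd == 2) rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
          else rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(mask, arr.ind = TRUE)
  if (nd == 2 && is.null(dim(idx))) idx <- matrix(idx, ncol = 2)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    on_surface <- FALSE
    for (o in seq_len(nrow(offs))) {
      nb <- v + offs[o, ]
      if (any(nb < 1) || any(nb > d)) { on_surface <- TRUE; break }
      inside <- if (nd == 2) mask[nb[1], nb[2]] else mask[nb[1], nb[2], nb[3]]
      if (!inside) { on_surface <- TRUE; break }
    }
    if (on_surface) pts <- rbind(pts, v * spacing)
  }
  pts
}

# directed distances by a double loop over surface point pairs
oracle_directed <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      dd <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (dd < best) best <- dd
    }
    best
  }, numeric(1))
}

oracle_hausdorff <- function(tm, nm, spacing, percentile = 100) {
  A <- oracle_surface(tm, spacing)
  B <- oracle_surface(nm, spacing)
  d_ab <- oracle_directed(A, B)
  d_ba <- oracle_directed(B, A)
  if (percentile == 100) max(max(d_ab), max(d_ba))
  else max(quantile(d_ab, percentile / 100, names = FALSE),
           quantile(d_ba, percentile / 100, names = FALSE))
}

# per-pixel weighted cross-entropy by explicit iteration
oracle_weighted_ce <- function(probs, target, phi) {
  d <- dim(probs)
  total <- 0
  n <- 0
  tgt <- as.vector(target)
  pm <- matrix(probs, nrow = d[1])
  for (x in seq_along(tgt)) {
    p <- max(pm[tgt[x] + 1, x], 1e-12)
    total <- total + (-phi[tgt[x] + 1] * log(p))
    n <- n + 1
  }
  total / n
}

# multi-class soft Dice loss evaluated class by class
oracle_dice_loss <- function(probs, target, eps = 1e-6) {
  P <- dim(probs)[1]
  pm <- matrix(probs, nrow = P)
  tgt <- as.vector(target)
  dice <- numeric(P)
  for (i in seq_len(P)) {
    t_i <- as.numeric(tgt == i - 1)
    p_i <- pm[i, ]
    dice[i] <- (2 * sum(p_i * t_i) + eps) / (sum(p_i) + sum(t_i) + eps)
  }
  1 - mean(dice)
}

# small random blob mask for metric tests
random_mask <- function(shape, n_seeds = 3) {
  m <- array(FALSE, dim = shape)
  for (s in seq_len(n_seeds)) {
    c0 <- sapply(shape, function(n) sample(seq_len(n), 1))
    r <- runif(1, 1, max(2, min(shape) / 3))
    idx <- which(array(TRUE, shape), arr.ind = TRUE)
    d2 <- rowSums(sweep(idx, 2, c0)^2)
    m[idx[d2 <= r^2, , drop = FALSE]] <- TRUE
  }
  m
}
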
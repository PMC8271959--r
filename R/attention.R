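# Spatial attention and atrous spatial pyramid pooling blocks.
#
# The spatial attention module (SAM) refines a feature map F in two steps:
#   F_supported = F (*) S(F)        channel gate, S(F) in [0,1]^{C x 1 x 1}
#   F_rs = F_supported (*) A_s(F_supported)   spatial gate in [0,1]^{1 x H x W}
# where (*) is element-wise multiplication with broadcasting. S(F) summarises
# each channel by the sum of its spatial mean and max passed through a
# sigmoid; A_s concatenates the channel-wise mean and max maps and passes
# them through a (default 7x7) convolution and a sigmoid.

#' Channel summary gate of the spatial attention module
#'
#' Computes the parameter-free channel gate `S(F)`: for each channel, the
#' spatial mean and spatial max are added and squashed through a sigmoid.
#'
#' @param f numeric array of dim `c(C, H, W)` (a feature map).
#' @return numeric array of dim `c(C, 1, 1)` with entries in `[0, 1]`.
#' @export
channel_summary <- function(f) {
  stopifnot(length(dim(f)) == 3L)
  x <- as_batch(f)
  ss <- spatial_stats(x)
  array(sigmoid(ss$mean + ss$max), dim = c(dim(f)[1], 1L, 1L))
}

#' Spatial attention map
#'
#' Channel-wise mean and max maps of `f` are concatenated (2 x H x W) and
#' convolved down to one channel with same-padding, then passed through a
#' sigmoid. The convolution weights default to a fresh fan-in initialisation
#' drawn from the current RNG state with a zero-initialised bias; pass a
#' `sam_block()` to reuse learned weights.
#'
#' @param f numeric array of dim `c(C, H, W)`.
#' @param kernel odd convolution kernel size (default 7).
#' @param sam optional `sam_block()` whose convolution is used.
#' @return numeric array of dim `c(1, H, W)` with entries in `[0, 1]`.
#' @export
spatial_attention_map <- function(f, kernel = 7L, sam = NULL) {
  stopifnot(length(dim(f)) == 3L)
  if (is.null(sam)) sam <- sam_block(kernel = kernel)
  x <- as_batch(f)
  cs <- channel_stats(x)
  d <- dim(x)
  g <- array(rbind(cs$mean, cs$max), dim = c(2L, d[2], d[3], d[4]))
  a <- sigmoid(sam$conv$forward(g, train = FALSE))
  array(a, dim = c(1L, d[2], d[3]))
}

#' Apply the spatial attention module to a feature map
#'
#' Runs the full two-gate refinement
#' `F_rs = (F (*) S(F)) (*) A_s(F (*) S(F))`. Both gates lie in `[0, 1]`, so
#' the output never exceeds the input in absolute value and the shape is
#' preserved.
#'
#' @inheritParams spatial_attention_map
#' @return array of the same dim as `f`.
#' @export
apply_sam <- function(f, kernel = 7L, sam = NULL) {
  stopifnot(length(dim(f)) == 3L)
  if (is.null(sam)) sam <- sam_block(kernel = kernel)
  y <- sam$forward(as_batch(f), train = FALSE)
  array(y, dim = dim(f))
}

#' Spatial attention module block
#'
#' The learnable SAM block used inside the decoder: a channel gate (sum of
#' spatial mean and max, sigmoid) followed by a spatial gate (channel
#' mean/max maps, `kernel` x `kernel` convolution with zero-initialised
#' bias, sigmoid).
#'
#' @param kernel odd convolution kernel size (default 7).
#' @return an internal module object with `$forward()`/`$backward()`.
#' @export
sam_block <- function(kernel = 7L) {
  if (kernel %% 2L == 0L) stop("sam_block: kernel size must be odd")
  m <- new_module("sam")
  m$conv <- conv_layer(2L, 1L, kernel, bias = TRUE)
  m$conv$b[] <- 0
  m$children <- list(m$conv)
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    d <- dim(x)
    ss <- spatial_stats(x)
    s <- matrix(sigmoid(ss$mean + ss$max), nrow = d[1])
    f1 <- mul_channel_gate(x, s)
    cs <- channel_stats(f1)
    g <- array(rbind(cs$mean, cs$max), dim = c(2L, d[2], d[3], d[4]))
    z <- m$conv$forward(g, train)
    a <- sigmoid(z)
    y <- mul_spatial_gate(f1, a)
    if (train) {
      m$x <- x; m$s <- s; m$f1 <- f1; m$a <- a
      m$sp_argmax <- ss$argmax; m$ch_argmax <- cs$argmax
    }
    y
  }
  m$backward <- function(dy) {
    d <- dim(m$x); C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
    # y = f1 * a, with a = sigmoid(conv(meanmap, maxmap))
    df1 <- mul_spatial_gate(dy, m$a)
    da <- .colSums(dy * m$f1, C, HW * N)
    dz <- da * as.vector(m$a) * (1 - as.vector(m$a))
    dim(dz) <- c(1L, d[2], d[3], N)
    dg <- m$conv$backward(dz)
    dgm <- matrix(dg, nrow = 2L)
    df1 <- df1 + rep(dgm[1L, ] / C, each = C)   # channel-mean map
    lin_max <- m$ch_argmax + C * (seq_len(HW * N) - 1L)
    df1[lin_max] <- df1[lin_max] + dgm[2L, ]    # channel-max map
    # f1 = x * s, with s = sigmoid(spatial mean + spatial max)
    dx <- mul_channel_gate(df1, m$s)
    ds <- .colSums(matrix(aperm(df1 * m$x, c(2, 3, 1, 4)), nrow = HW), HW, C * N)
    dpre <- ds * as.vector(m$s) * (1 - as.vector(m$s))
    gm <- matrix(dpre / HW, nrow = C)
    dx <- dx + as.vector(gm[, rep(seq_len(N), each = HW), drop = FALSE])
    cidx <- rep(seq_len(C), N)
    nidx <- rep(seq_len(N), each = C)
    lin_sp <- cidx + C * (m$sp_argmax - 1L) + C * HW * (nidx - 1L)
    dx[lin_sp] <- dx[lin_sp] + dpre
    m$x <- NULL; m$f1 <- NULL; m$a <- NULL
    dx
  }
  m
}

# global average pool to (C,1,1,N) and its broadcast inverse
gap_layer <- function() {
  m <- new_module("gap")
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    d <- dim(x)
    if (train) m$xdim <- d
    z <- .colSums(matrix(aperm(x, c(2, 3, 1, 4)), nrow = d[2] * d[3]),
                  d[2] * d[3], d[1] * d[4]) / (d[2] * d[3])
    array(z, dim = c(d[1], 1L, 1L, d[4]))
  }
  m$backward <- function(dy) {
    d <- m$xdim
    g <- matrix(as.vector(dy) / (d[2] * d[3]), nrow = d[1])
    array(as.vector(g[, rep(seq_len(d[4]), each = d[2] * d[3]), drop = FALSE]), dim = d)
  }
  m
}

cat_channels <- function(xs) {
  dims <- lapply(xs, dim)
  C <- sum(vapply(dims, `[`, integer(1), 1L))
  d1 <- dims[[1]]
  out <- array(0, dim = c(C, d1[2], d1[3], d1[4]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

split_channels <- function(dy, widths) {
  at <- 0L
  out <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    out[[i]] <- dy[at + seq_len(widths[i]), , , , drop = FALSE]
    at <- at + widths[i]
  }
  out
}

#' Atrous spatial pyramid pooling block
#'
#' Parallel branches over the input: a 1x1 convolution, one 3x3 dilated
#' convolution per entry of `rates`, and a global-average-pooling branch,
#' each followed by GroupNorm and ReLU; branch outputs are concatenated and
#' projected back to `out_ch` channels by a 1x1 convolution. Spatial size is
#' preserved. Used at the encoder/decoder bottleneck to enlarge the
#' receptive field.
#'
#' @param in_ch,out_ch input/output channel counts.
#' @param rates non-empty integer vector of dilation rates (default 6,12,18).
#' @param norm a [norm_spec()].
#' @return an internal module object.
#' @export
aspp_block <- function(in_ch, out_ch, rates = c(6L, 12L, 18L), norm = norm_spec()) {
  if (length(rates) == 0L) stop("aspp_block: rates must be non-empty")
  m <- new_module("aspp")
  mk_branch <- function(k, dil) {
    sequential_module(
      conv_layer(in_ch, out_ch, k, pad = if (k == 1L) 0L else dil, dilation = dil),
      norm_layer(out_ch, norm), relu_layer())
  }
  m$branches <- c(list(mk_branch(1L, 1L)),
                  lapply(as.integer(rates), function(r) mk_branch(3L, r)))
  m$gap <- gap_layer()
  m$gp_conv <- sequential_module(conv_layer(in_ch, out_ch, 1L, pad = 0L),
                                 norm_layer(out_ch, norm), relu_layer())
  n_branch <- length(m$branches) + 1L
  m$proj <- sequential_module(conv_layer(n_branch * out_ch, out_ch, 1L, pad = 0L),
                              norm_layer(out_ch, norm), relu_layer())
  m$out_ch <- out_ch
  m$children <- c(m$branches, list(m$gap, m$gp_conv, m$proj))
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    d <- dim(x)
    outs <- lapply(m$branches, function(b) b$forward(x, train))
    z <- m$gp_conv$forward(m$gap$forward(x, train), train)  # (out_ch,1,1,N)
    zb <- array(0, dim = c(m$out_ch, d[2], d[3], d[4]))
    for (n in seq_len(d[4])) zb[, , , n] <- z[, 1, 1, n]
    if (train) m$bdim <- dim(zb)
    m$proj$forward(cat_channels(c(outs, list(zb))), train)
  }
  m$backward <- function(dy) {
    dcat <- m$proj$backward(dy)
    widths <- rep(m$out_ch, length(m$branches) + 1L)
    parts <- split_channels(dcat, widths)
    dx <- 0
    for (i in seq_along(m$branches))
      dx <- dx + m$branches[[i]]$backward(parts[[i]])
    dzb <- parts[[length(parts)]]
    d <- m$bdim
    dz <- array(.colSums(matrix(aperm(array(dzb, d), c(2, 3, 1, 4)), nrow = d[2] * d[3]),
                         d[2] * d[3], d[1] * d[4]),
                dim = c(d[1], 1L, 1L, d[4]))
    dx + m$gap$backward(m$gp_conv$backward(dz))
  }
  m
}
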
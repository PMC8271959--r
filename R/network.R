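# Full segmentation network: backbone encoder -> ASPP bottleneck ->
# dual-branch group-normalized decoder with spatial attention -> softmax head.
#
# Encoder stage widths (m0..m4): (64, 64, 128, 256, 512) for resnet34 and
# (64, 256, 512, 1024, 2048) for seresnext50. Decoder widths (m'0..m'4) are
# (256, 128, 64, 32, 16) for both; stage i consumes the upsampled previous
# output concatenated with encoder skip m3, m2, m1, m0, and the last stage
# takes no skip.

#' Backbone specification
#'
#' @param name `"resnet34"` or `"seresnext50"`.
#' @param pretrained logical; when `TRUE` the caller is expected to load
#'   externally converted ImageNet convolution weights into the checkpoint
#'   (normalisation statistics are always re-initialised since BatchNorm
#'   layers are replaced by GroupNorm). Tests and the phantom pipeline use
#'   random initialisation.
#' @return a `backbone_spec` list with the five encoder stage widths.
#' @export
backbone_spec <- function(name = c("resnet34", "seresnext50"), pretrained = FALSE) {
  name <- match.arg(name)
  stage_channels <- switch(name,
    resnet34 = c(64L, 64L, 128L, 256L, 512L),
    seresnext50 = c(64L, 256L, 512L, 1024L, 2048L))
  structure(list(name = name, stage_channels = stage_channels,
                 pretrained = pretrained),
            class = "backbone_spec")
}

#' Normalisation specification
#'
#' @param kind `"group"` (default; batch-size independent) or `"batch"`.
#' @param groups group count for GroupNorm; `NULL` picks the largest
#'   divisor of each layer's channel count not exceeding 32.
#' @return a `norm_spec` list.
#' @export
norm_spec <- function(kind = c("group", "batch"), groups = NULL) {
  kind <- match.arg(kind)
  if (!is.null(groups) && groups < 1L) stop("norm_spec: groups must be positive")
  structure(list(kind = kind, groups = groups), class = "norm_spec")
}

decoder_plan <- function() c(256L, 128L, 64L, 32L, 16L)

# --- residual blocks -------------------------------------------------------

basic_block <- function(in_ch, out_ch, stride, norm) {
  m <- new_module("basic_block")
  m$c1 <- conv_layer(in_ch, out_ch, 3L, stride = stride)
  m$n1 <- norm_layer(out_ch, norm)
  m$r1 <- relu_layer()
  m$c2 <- conv_layer(out_ch, out_ch, 3L)
  m$n2 <- norm_layer(out_ch, norm)
  m$r2 <- relu_layer()
  m$down <- if (stride != 1L || in_ch != out_ch)
    sequential_module(conv_layer(in_ch, out_ch, 1L, stride = stride, pad = 0L),
                      norm_layer(out_ch, norm))
  else NULL
  m$children <- c(list(m$c1, m$n1, m$r1, m$c2, m$n2, m$r2),
                  if (!is.null(m$down)) list(m$down))
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    h <- m$n2$forward(m$c2$forward(m$r1$forward(m$n1$forward(m$c1$forward(x, train), train), train), train), train)
    sc <- if (is.null(m$down)) x else m$down$forward(x, train)
    m$r2$forward(h + sc, train)
  }
  m$backward <- function(dy) {
    d <- m$r2$backward(dy)
    dx_main <- m$c1$backward(m$n1$backward(m$r1$backward(m$c2$backward(m$n2$backward(d)))))
    dx_sc <- if (is.null(m$down)) d else m$down$backward(d)
    dx_main + dx_sc
  }
  m
}

se_module <- function(channels, reduction = 16L) {
  m <- new_module("se")
  mid <- max(channels %/% reduction, 1L)
  m$gap <- gap_layer()
  m$fc1 <- conv_layer(channels, mid, 1L, pad = 0L, bias = TRUE)
  m$r <- relu_layer()
  m$fc2 <- conv_layer(mid, channels, 1L, pad = 0L, bias = TRUE)
  m$children <- list(m$gap, m$fc1, m$r, m$fc2)
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    z <- m$fc2$forward(m$r$forward(m$fc1$forward(m$gap$forward(x, train), train), train), train)
    a <- sigmoid(z)  # (C,1,1,N)
    d <- dim(x)
    g <- matrix(as.vector(a), nrow = d[1])
    y <- mul_channel_gate(x, g)
    if (train) { m$x <- x; m$a <- a; m$g <- g }
    y
  }
  m$backward <- function(dy) {
    d <- dim(m$x)
    dx <- mul_channel_gate(dy, m$g)
    da <- .colSums(matrix(aperm(dy * m$x, c(2, 3, 1, 4)), nrow = d[2] * d[3]),
                   d[2] * d[3], d[1] * d[4])
    dz <- da * as.vector(m$a) * (1 - as.vector(m$a))
    dim(dz) <- c(d[1], 1L, 1L, d[4])
    dx2 <- m$gap$backward(m$fc1$backward(m$r$backward(m$fc2$backward(dz))))
    m$x <- NULL; m$a <- NULL
    dx + dx2
  }
  m
}

se_bottleneck <- function(in_ch, out_ch, stride, cardinality, norm, reduction = 16L) {
  mid <- out_ch %/% 2L  # resnext 32x4d width rule
  m <- new_module("se_bottleneck")
  m$c1 <- conv_layer(in_ch, mid, 1L, pad = 0L)
  m$n1 <- norm_layer(mid, norm); m$r1 <- relu_layer()
  m$c2 <- conv_layer(mid, mid, 3L, stride = stride, groups = cardinality)
  m$n2 <- norm_layer(mid, norm); m$r2 <- relu_layer()
  m$c3 <- conv_layer(mid, out_ch, 1L, pad = 0L)
  m$n3 <- norm_layer(out_ch, norm)
  m$se <- se_module(out_ch, reduction)
  m$r3 <- relu_layer()
  m$down <- if (stride != 1L || in_ch != out_ch)
    sequential_module(conv_layer(in_ch, out_ch, 1L, stride = stride, pad = 0L),
                      norm_layer(out_ch, norm))
  else NULL
  m$children <- c(list(m$c1, m$n1, m$r1, m$c2, m$n2, m$r2, m$c3, m$n3, m$se, m$r3),
                  if (!is.null(m$down)) list(m$down))
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    h <- m$r1$forward(m$n1$forward(m$c1$forward(x, train), train), train)
    h <- m$r2$forward(m$n2$forward(m$c2$forward(h, train), train), train)
    h <- m$se$forward(m$n3$forward(m$c3$forward(h, train), train), train)
    sc <- if (is.null(m$down)) x else m$down$forward(x, train)
    m$r3$forward(h + sc, train)
  }
  m$backward <- function(dy) {
    d <- m$r3$backward(dy)
    dh <- m$se$backward(d)
    dh <- m$c3$backward(m$n3$backward(dh))
    dh <- m$c2$backward(m$n2$backward(m$r2$backward(dh)))
    dx_main <- m$c1$backward(m$n1$backward(m$r1$backward(dh)))
    dx_sc <- if (is.null(m$down)) d else m$down$backward(d)
    dx_main + dx_sc
  }
  m
}

# --- encoders --------------------------------------------------------------

make_encoder <- function(backbone, norm) {
  m <- new_module(paste0("encoder_", backbone$name))
  ch <- backbone$stage_channels
  m$stage0 <- sequential_module(conv_layer(3L, ch[1], 7L, stride = 2L, pad = 3L),
                                norm_layer(ch[1], norm), relu_layer())
  m$pool <- maxpool_layer(3L, 2L, 1L)
  if (backbone$name == "resnet34") {
    counts <- c(3L, 4L, 6L, 3L)
    mk_stage <- function(in_ch, out_ch, n, stride) {
      blocks <- list(basic_block(in_ch, out_ch, stride, norm))
      for (i in seq_len(n - 1L)) blocks <- c(blocks, list(basic_block(out_ch, out_ch, 1L, norm)))
      sequential_module(blocks)
    }
  } else {
    counts <- c(3L, 4L, 6L, 3L)
    mk_stage <- function(in_ch, out_ch, n, stride) {
      blocks <- list(se_bottleneck(in_ch, out_ch, stride, 32L, norm))
      for (i in seq_len(n - 1L)) blocks <- c(blocks, list(se_bottleneck(out_ch, out_ch, 1L, 32L, norm)))
      sequential_module(blocks)
    }
  }
  m$stage1 <- mk_stage(ch[1], ch[2], counts[1], 1L)
  m$stage2 <- mk_stage(ch[2], ch[3], counts[2], 2L)
  m$stage3 <- mk_stage(ch[3], ch[4], counts[3], 2L)
  m$stage4 <- mk_stage(ch[4], ch[5], counts[4], 2L)
  m$children <- list(m$stage0, m$pool, m$stage1, m$stage2, m$stage3, m$stage4)
  m$forward_stages <- function(x, train = FALSE) {
    s0 <- m$stage0$forward(x, train)
    s1 <- m$stage1$forward(m$pool$forward(s0, train), train)
    s2 <- m$stage2$forward(s1, train)
    s3 <- m$stage3$forward(s2, train)
    s4 <- m$stage4$forward(s3, train)
    list(s0, s1, s2, s3, s4)
  }
  m$backward_stages <- function(ds) {
    d4 <- m$stage4$backward(ds[[5]])
    d3 <- m$stage3$backward(d4 + ds[[4]])
    d2 <- m$stage2$backward(d3 + ds[[3]])
    d1 <- m$stage1$backward(d2 + ds[[2]])
    d0 <- m$pool$backward(d1)
    m$stage0$backward(d0 + ds[[1]])
  }
  m
}

# --- decoder ---------------------------------------------------------------

#' Dual-branch decoder stage
#'
#' Upsamples the previous decoder output by 2 (bilinear), concatenates the
#' encoder skip (when present), and merges two branches by element-wise
#' addition: branch 1 is two 3x3 Conv-GroupNorm-ReLU blocks followed by a
#' spatial attention module; branch 2 is a single 1x1 Conv-GroupNorm block.
#'
#' @param in_ch channels after upsample + skip concatenation.
#' @param out_ch output channels of the stage.
#' @param norm a [norm_spec()].
#' @param sam_kernel kernel size of the SAM convolution.
#' @return an internal module; `$forward(prev, skip, train)` and
#'   `$backward(dy)` (returning `list(dprev, dskip)`).
#' @export
decoder_stage <- function(in_ch, out_ch, norm = norm_spec(), sam_kernel = 7L) {
  m <- new_module("decoder_stage")
  m$up <- upsample2x_layer()
  m$b1 <- sequential_module(
    conv_layer(in_ch, out_ch, 3L), norm_layer(out_ch, norm), relu_layer(),
    conv_layer(out_ch, out_ch, 3L), norm_layer(out_ch, norm), relu_layer())
  m$sam <- sam_block(sam_kernel)
  m$b2 <- sequential_module(conv_layer(in_ch, out_ch, 1L, pad = 0L),
                            norm_layer(out_ch, norm))
  m$children <- list(m$up, m$b1, m$sam, m$b2)
  m$forward <- function(prev, skip = NULL, train = FALSE) {
    up <- m$up$forward(as_batch(prev), train)
    if (!is.null(skip)) {
      skip <- as_batch(skip)
      if (!all(dim(up)[2:3] == dim(skip)[2:3]))
        stop("decoder_stage: skip spatial size must be twice the previous stage")
      x <- cat_channels(list(up, skip))
      m$widths <- c(dim(up)[1], dim(skip)[1])
    } else {
      x <- up
      m$widths <- NULL
    }
    y1 <- m$sam$forward(m$b1$forward(x, train), train)
    y2 <- m$b2$forward(x, train)
    y1 + y2
  }
  m$backward <- function(dy) {
    dx <- m$b1$backward(m$sam$backward(dy)) + m$b2$backward(dy)
    if (!is.null(m$widths)) {
      parts <- split_channels(dx, m$widths)
      dprev <- m$up$backward(parts[[1]])
      list(dprev = dprev, dskip = parts[[2]])
    } else {
      list(dprev = m$up$backward(dx), dskip = NULL)
    }
  }
  m
}

# --- full network ----------------------------------------------------------

#' Build the segmentation network
#'
#' Assembles encoder, ASPP bottleneck (dilation rates 6/12/18, output width
#' equal to the deepest encoder width), five decoder stages and a 1x1
#' classification head producing per-pixel class probabilities via softmax.
#'
#' @param backbone a [backbone_spec()].
#' @param num_classes number of classes P (>= 2), background included.
#' @param norm a [norm_spec()].
#' @param aspp_rates dilation rates of the bottleneck ASPP block.
#' @param sam_kernel SAM convolution kernel size.
#' @return an `oar_network` object.
#' @export
build_network <- function(backbone = backbone_spec("resnet34"), num_classes = 5L,
                          norm = norm_spec(), aspp_rates = c(6L, 12L, 18L),
                          sam_kernel = 7L) {
  if (num_classes < 2L) stop("build_network: num_classes must be >= 2")
  stopifnot(inherits(backbone, "backbone_spec"))
  ch <- backbone$stage_channels
  dp <- decoder_plan()
  net <- new_module("network")
  net$backbone <- backbone
  net$num_classes <- as.integer(num_classes)
  net$norm <- norm
  net$aspp_rates <- as.integer(aspp_rates)
  net$sam_kernel <- as.integer(sam_kernel)
  net$encoder <- make_encoder(backbone, norm)
  net$aspp <- aspp_block(ch[5], ch[5], aspp_rates, norm)
  in_ch <- c(ch[5] + ch[4], dp[1] + ch[3], dp[2] + ch[2], dp[3] + ch[1], dp[4])
  net$decoders <- lapply(1:5, function(i)
    decoder_stage(in_ch[i], dp[i], norm, sam_kernel))
  net$head <- conv_layer(dp[5], num_classes, 1L, pad = 0L, bias = TRUE)
  # class-imbalance-aware head initialisation: start from ~90% background
  # so the rare-class Dice gradients concentrate on true foreground voxels
  # instead of first growing and then shrinking a large false-positive blob
  net$head$b <- log(c(0.9, rep(0.1 / (num_classes - 1), num_classes - 1)))
  net$children <- c(list(net$encoder, net$aspp), net$decoders, list(net$head))
  class(net) <- c("oar_network", class(net))
  net
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[1])
  m <- exp(sweep(m, 2L, apply(m, 2L, max), "-"))
  m <- sweep(m, 2L, colSums(m), "/")
  array(m, dim = d)
}

forward_logits <- function(net, x, train = FALSE) {
  x <- as_batch(x)
  s <- net$encoder$forward_stages(x, train)
  b <- net$aspp$forward(s[[5]], train)
  d0 <- net$decoders[[1]]$forward(b, s[[4]], train)
  d1 <- net$decoders[[2]]$forward(d0, s[[3]], train)
  d2 <- net$decoders[[3]]$forward(d1, s[[2]], train)
  d3 <- net$decoders[[4]]$forward(d2, s[[1]], train)
  d4 <- net$decoders[[5]]$forward(d3, NULL, train)
  net$head$forward(d4, train)
}

backward_logits <- function(net, dlogits) {
  dd4 <- net$head$backward(dlogits)
  g4 <- net$decoders[[5]]$backward(dd4)
  g3 <- net$decoders[[4]]$backward(g4$dprev)
  g2 <- net$decoders[[3]]$backward(g3$dprev)
  g1 <- net$decoders[[2]]$backward(g2$dprev)
  g0 <- net$decoders[[1]]$backward(g1$dprev)
  db <- net$aspp$backward(g0$dprev)
  ds <- list(g3$dskip, g2$dskip, g1$dskip, g0$dskip, db)
  net$encoder$backward_stages(ds)
}

#' Forward pass producing per-pixel class probabilities
#'
#' Inputs whose height or width is not divisible by 32 (the encoder stride
#' product) are symmetrically zero-padded and the output cropped back, so
#' the output spatial size always equals the input size. Per-pixel
#' probabilities sum to 1.
#'
#' @param net an `oar_network`.
#' @param x array `c(3, H, W)` or batch `c(3, H, W, N)` of normalised slices.
#' @param train logical; caches intermediates for backprop when `TRUE`.
#' @return probability array `c(num_classes, H, W)` (or with batch axis).
#' @export
network_forward <- function(net, x, train = FALSE) {
  single <- length(dim(x)) == 3L
  x <- as_batch(x)
  d <- dim(x)
  H <- d[2]; W <- d[3]
  padH <- (32L - H %% 32L) %% 32L
  padW <- (32L - W %% 32L) %% 32L
  if (padH > 0L || padW > 0L) {
    if (train) stop("network_forward: training inputs must be divisible by 32")
    xp <- array(0, dim = c(d[1], H + padH, W + padW, d[4]))
    oh <- padH %/% 2L; ow <- padW %/% 2L
    xp[, oh + seq_len(H), ow + seq_len(W), ] <- x
    logits <- forward_logits(net, xp, train = FALSE)
    logits <- logits[, oh + seq_len(H), ow + seq_len(W), , drop = FALSE]
  } else {
    logits <- forward_logits(net, x, train = train)
  }
  probs <- softmax_channels(logits)
  if (single) array(probs, dim = dim(probs)[1:3]) else probs
}

#' Save / load a network checkpoint
#'
#' Checkpoints store every weight plus the full configuration (backbone,
#' normalisation, class count, window), so inference can rebuild the network
#' without the training config.
#'
#' @param net an `oar_network`.
#' @param path file path (`.rds`).
#' @param window optional [window_spec()] stored for inference preprocessing.
#' @param extra optional list of additional metadata to store.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with elements `net`, `window`, `extra`.
#' @export
save_checkpoint <- function(net, path, window = NULL, extra = list()) {
  obj <- list(backbone = net$backbone$name,
              pretrained = net$backbone$pretrained,
              num_classes = net$num_classes,
              norm = unclass(net$norm),
              aspp_rates = net$aspp_rates,
              sam_kernel = net$sam_kernel,
              window = if (is.null(window)) NULL else unclass(window),
              state = module_state(net),
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- build_network(backbone_spec(obj$backbone, obj$pretrained),
                       num_classes = obj$num_classes,
                       norm = norm_spec(obj$norm$kind, obj$norm$groups),
                       aspp_rates = obj$aspp_rates,
                       sam_kernel = obj$sam_kernel)
  load_module_state(net, obj$state)
  window <- if (is.null(obj$window)) NULL else window_spec(obj$window$lower, obj$window$upper)
  list(net = net, window = window, extra = obj$extra)
}
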
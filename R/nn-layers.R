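#' @useDynLib oarseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Minimal define-by-module neural blocks with explicit backprop.
#
# Every module is an environment with:
#   $forward(x, train)  -> output, caching whatever backward needs
#   $backward(dy)       -> gradient w.r.t. its input; parameter gradients are
#                          stored in the module as g<name>
#   $params             -> character vector of parameter field names
#   $children           -> list of sub-modules (for parameter collection)
# Tensors are numeric arrays with dim c(C, H, W, N).
# ---------------------------------------------------------------------------

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- character(0)
  e$children <- list()
  class(e) <- c(paste0("oar_", type), "oar_module")
  e
}

#' @export
print.oar_module <- function(x, ...) {
  cat("<oarseg module:", x$type, ">\n")
  invisible(x)
}

as_batch <- function(x) {
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
  }
  x
}

# He-normal initialisation for a conv weight in GEMM layout:
# a (Cg*kh*kw) x Cout matrix, group g owning the contiguous column block.
init_conv_weight <- function(out_ch, in_g, kh, kw) {
  fan_in <- in_g * kh * kw
  matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
         nrow = fan_in, ncol = out_ch)
}

conv_layer <- function(in_ch, out_ch, kernel, stride = 1L, pad = kernel %/% 2L,
                       dilation = 1L, groups = 1L, bias = FALSE,
                       zero_init = FALSE) {
  if (in_ch %% groups != 0L || out_ch %% groups != 0L)
    stop("conv_layer: channels not divisible by groups")
  m <- new_module("conv")
  m$W <- init_conv_weight(out_ch, in_ch %/% groups, kernel, kernel)
  if (zero_init) m$W[] <- 0
  m$kdim <- c(as.integer(kernel), as.integer(kernel))
  m$b <- if (bias) numeric(out_ch) else NULL
  m$params <- if (bias) c("W", "b") else "W"
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$dilation <- as.integer(dilation); m$groups <- as.integer(groups)
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    if (train) m$x <- x
    .conv2d_fwd(x, m$W, m$b, m$kdim, m$stride, m$pad, m$dilation, m$groups)
  }
  m$backward <- function(dy, need_dx = TRUE) {
    g <- .conv2d_bwd(m$x, m$W, dy, m$kdim, m$stride, m$pad, m$dilation,
                     m$groups, need_dx)
    m$gW <- g$dw
    if (!is.null(m$b)) m$gb <- g$db
    m$x <- NULL
    if (need_dx) g$dx else NULL
  }
  m
}

# Largest group count dividing the channel width, capped at 32.
gn_groups <- function(channels) {
  g <- 32L
  while (channels %% g != 0L) g <- g %/% 2L
  max(g, 1L)
}

groupnorm_layer <- function(channels, groups = gn_groups(channels), eps = 1e-5) {
  if (channels %% groups != 0L)
    stop("groupnorm_layer: groups must divide the channel count")
  m <- new_module("groupnorm")
  m$gamma <- rep(1, channels); m$beta <- numeric(channels)
  m$groups <- as.integer(groups); m$eps <- eps
  m$params <- c("gamma", "beta")
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    out <- .gn_fwd(x, m$gamma, m$beta, m$groups, m$eps)
    if (train) { m$x <- x; m$mean <- out$mean; m$invstd <- out$invstd }
    out$y
  }
  m$backward <- function(dy) {
    g <- .gn_bwd(m$x, dy, m$gamma, m$mean, m$invstd, m$groups)
    m$ggamma <- g$dgamma; m$gbeta <- g$dbeta
    m$x <- NULL
    g$dx
  }
  m
}

# BatchNorm is kept for the norm-comparison configuration; evaluation mode
# uses running statistics so inference is batch-independent too, but the
# training statistics are batch-coupled (the property GroupNorm avoids).
batchnorm_layer <- function(channels, eps = 1e-5, momentum = 0.1) {
  m <- new_module("batchnorm")
  m$gamma <- rep(1, channels); m$beta <- numeric(channels)
  m$run_mean <- numeric(channels); m$run_var <- rep(1, channels)
  m$eps <- eps; m$momentum <- momentum
  m$params <- c("gamma", "beta")
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    d <- dim(x); C <- d[1]
    xm <- matrix(aperm(x, c(2, 3, 4, 1)), ncol = C)
    if (train) {
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      m$run_mean <- (1 - m$momentum) * m$run_mean + m$momentum * mu
      m$run_var <- (1 - m$momentum) * m$run_var + m$momentum * v
      m$x <- x; m$mu <- mu; m$invstd <- 1 / sqrt(v + m$eps)
    } else {
      mu <- m$run_mean
      v <- m$run_var
    }
    istd <- 1 / sqrt(v + m$eps)
    y <- (x - rep(mu, length.out = length(x))) * rep(m$gamma * istd, length.out = length(x)) +
      rep(m$beta, length.out = length(x))
    dim(y) <- d
    y
  }
  m$backward <- function(dy) {
    d <- dim(m$x); C <- d[1]; M <- prod(d[-1])
    xh <- (m$x - rep(m$mu, length.out = length(m$x))) * rep(m$invstd, length.out = length(m$x))
    dxh <- dy * rep(m$gamma, length.out = length(dy))
    per_ch <- function(a) .rowSums(a, C, M)
    s1 <- per_ch(dxh); s2 <- per_ch(dxh * xh)
    m$ggamma <- per_ch(dy * xh); m$gbeta <- per_ch(dy)
    dx <- rep(m$invstd, length.out = length(dy)) / M *
      (M * dxh - rep(s1, length.out = length(dy)) - xh * rep(s2, length.out = length(dy)))
    dim(dx) <- d
    m$x <- NULL
    dx
  }
  m
}

norm_layer <- function(channels, norm) {
  if (norm$kind == "group") {
    g <- if (is.null(norm$groups)) gn_groups(channels) else {
      if (channels %% norm$groups == 0L) norm$groups else gn_groups(channels)
    }
    groupnorm_layer(channels, groups = g)
  } else {
    batchnorm_layer(channels)
  }
}

relu_layer <- function() {
  m <- new_module("relu")
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    if (train) m$mask <- x > 0
    x * (x > 0)
  }
  m$backward <- function(dy) {
    dx <- dy * m$mask
    m$mask <- NULL
    dx
  }
  m
}

maxpool_layer <- function(kernel = 3L, stride = 2L, pad = 1L) {
  m <- new_module("maxpool")
  m$kernel <- as.integer(kernel); m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    out <- .maxpool_fwd(x, m$kernel, m$stride, m$pad)
    if (train) { m$idx <- out$idx; m$xdim <- dim(x) }
    out$y
  }
  m$backward <- function(dy) {
    dx <- .maxpool_bwd(dy, m$idx, m$xdim)
    m$idx <- NULL
    dx
  }
  m
}

upsample2x_layer <- function() {
  m <- new_module("upsample2x")
  m$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    if (train) m$xdim <- dim(x)
    .upsample2x_fwd(x)
  }
  m$backward <- function(dy) .upsample2x_bwd(dy, m$xdim)
  m
}

sequential_module <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "oar_module"))
    mods <- mods[[1]]
  m <- new_module("sequential")
  m$children <- mods
  m$forward <- function(x, train = FALSE) {
    for (ch in m$children) x <- ch$forward(x, train)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}

# --- broadcast helpers -----------------------------------------------------

# multiply (C,H,W,N) by a per-(channel, sample) gate of dim (C,N)
mul_channel_gate <- function(x, g) {
  d <- dim(x)
  y <- x
  hw <- d[2] * d[3]
  gexp <- g[, rep(seq_len(d[4]), each = hw), drop = FALSE]
  y * as.vector(gexp)
}

# multiply (C,H,W,N) by a per-(pixel, sample) gate of length H*W*N
mul_spatial_gate <- function(x, a) {
  x * rep(as.vector(a), each = dim(x)[1])
}

# mean and max (with argmax) over the spatial axes, per channel and sample
spatial_stats <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(2, 3, 1, 4)), nrow = d[2] * d[3])
  amax <- max.col(t(m), ties.method = "first")
  list(mean = colMeans(m),
       max = m[cbind(amax, seq_len(ncol(m)))],
       argmax = amax, dim = d)
}

# mean and max (with argmax) over the channel axis, per pixel and sample
channel_stats <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1])
  amax <- max.col(t(m), ties.method = "first")
  list(mean = colMeans(m),
       max = m[cbind(amax, seq_len(ncol(m)))],
       argmax = amax, dim = d)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- parameter collection / optimiser --------------------------------------

collect_param_refs <- function(module, acc = NULL) {
  if (is.null(acc)) acc <- list()
  for (p in module$params) acc[[length(acc) + 1L]] <- list(env = module, name = p)
  for (ch in module$children) acc <- collect_param_refs(ch, acc)
  acc
}

count_parameters <- function(module) {
  refs <- collect_param_refs(module)
  sum(vapply(refs, function(r) length(r$env[[r$name]]), numeric(1)))
}

adam_optimizer <- function(module, lr = 3e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$refs <- collect_param_refs(module)
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  zeros <- function(r) array(0, dim = dim(r$env[[r$name]]) %||% length(r$env[[r$name]]))
  opt$m <- lapply(opt$refs, zeros)
  opt$v <- lapply(opt$refs, zeros)  # distinct buffers: updates are in place
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$env[[paste0("g", r$name)]]
    if (is.null(g)) next
    .adam_update(r$env[[r$name]], g, opt$m[[i]], opt$v[[i]],
                 opt$lr, opt$beta1, opt$beta2, opt$eps, opt$t)
  }
  invisible(opt)
}

# --- (de)serialisable state ------------------------------------------------

module_state <- function(module) {
  st <- list()
  grab <- function(m, prefix) {
    fields <- c(m$params, intersect(c("run_mean", "run_var"), ls(m)))
    for (p in fields) st[[paste0(prefix, p)]] <<- m[[p]]
    for (i in seq_along(m$children))
      grab(m$children[[i]], paste0(prefix, i, "."))
  }
  grab(module, "")
  st
}

load_module_state <- function(module, state) {
  put <- function(m, prefix) {
    fields <- c(m$params, intersect(c("run_mean", "run_var"), ls(m)))
    for (p in fields) {
      key <- paste0(prefix, p)
      if (!key %in% names(state)) stop("checkpoint state missing field ", key)
      stopifnot(length(state[[key]]) == length(m[[p]]))
      m[[p]] <- state[[key]] + 0  # force a copy: parameters are updated in place
    }
    for (i in seq_along(m$children))
      put(m$children[[i]], paste0(prefix, i, "."))
  }
  put(module, "")
  invisible(module)
}
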
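# Dense-array neural-network primitives.
#
# Feature maps are arrays of dim c(H, W, C); token matrices are [N, C].
# Convolution weights are arrays c(kh, kw, in, out) so that the column-major
# flattening matrix(w, kh*kw*in, out) matches the im2col column ordering
# (kernel row fastest, then kernel col, then channel).

#' Run an expression with a temporarily seeded RNG
#'
#' Saves and restores `.Random.seed` so library calls do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

zero_pad_hw <- function(x, pad) {
  if (pad <= 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# Column index matrix for im2col: rows index output pixels (out-row fastest),
# columns index (kernel-row, kernel-col, channel).
im2col_index <- function(H, W, C, kh, kw, stride) {
  oh <- (H - kh) %/% stride + 1L
  ow <- (W - kw) %/% stride + 1L
  oi <- (seq_len(oh) - 1L) * stride          # 0-based top-left row
  oj <- (seq_len(ow) - 1L) * stride
  ii <- rep(oi, times = ow)
  jj <- rep(oj, each = oh)
  off <- expand.grid(di = seq_len(kh), dj = seq_len(kw), c = seq_len(C))
  idx <- outer(ii, off$di, `+`) +
    H * outer(jj, off$dj - 1L, `+`) +
    (H * W) * matrix(off$c - 1L, nrow = oh * ow, ncol = nrow(off), byrow = TRUE)
  list(idx = idx, oh = oh, ow = ow)
}

im2col <- function(x, kh, kw, stride = 1L, pad = 0L) {
  x <- zero_pad_hw(x, pad)
  d <- dim(x)
  ix <- im2col_index(d[1], d[2], d[3], kh, kw, stride)
  # index with a plain vector: a K-column index matrix on a K-d array would
  # otherwise be read as coordinate rows
  list(cols = matrix(x[as.vector(ix$idx)], nrow(ix$idx), ncol(ix$idx)),
       idx = ix$idx, oh = ix$oh, ow = ix$ow,
       Hp = d[1], Wp = d[2], C = d[3])
}

#' 2-D convolution forward pass
#' @param x input array c(H, W, C_in).
#' @param w weight array c(kh, kw, C_in, C_out).
#' @param b bias vector length C_out or `NULL`.
#' @param stride,pad integer stride and symmetric zero padding.
#' @param cache return the im2col cache for a later backward pass?
#' @return array c(H_out, W_out, C_out); with `cache = TRUE`, a list
#'   `(out, cache)`.
#' @keywords internal
conv2d_fwd <- function(x, w, b = NULL, stride = 1L, pad = 0L, cache = FALSE) {
  dw <- dim(w)
  ic <- im2col(x, dw[1], dw[2], stride = stride, pad = pad)
  wm <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  y <- ic$cols %*% wm
  if (!is.null(b)) y <- sweep(y, 2L, b, `+`)
  out <- array(y, c(ic$oh, ic$ow, dw[4]))
  if (!cache) return(out)
  list(out = out, cache = list(ic = ic, wdim = dw, pad = pad, xdim = dim(x)))
}

# Backward for conv2d_fwd: returns list(dw, db, dx); dx omitted when
# need_dx = FALSE (cheaper for first layers whose input is frozen).
conv2d_bwd <- function(dy, w, cache, need_dx = TRUE) {
  dw_dim <- cache$wdim
  ic <- cache$ic
  dym <- matrix(dy, ic$oh * ic$ow, dw_dim[4])
  dw <- array(crossprod(ic$cols, dym), dw_dim)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    wm <- matrix(w, dw_dim[1] * dw_dim[2] * dw_dim[3], dw_dim[4])
    m <- tcrossprod(dym, wm)                      # [P, K] grads w.r.t. cols
    dxp <- numeric(ic$Hp * ic$Wp * ic$C)
    agg <- rowsum(c(m), group = c(ic$idx), reorder = FALSE)
    dxp[as.integer(rownames(agg))] <- agg
    dxp <- array(dxp, c(ic$Hp, ic$Wp, ic$C))
    p <- cache$pad
    if (p > 0) {
      d0 <- cache$xdim
      dxp <- dxp[p + seq_len(d0[1]), p + seq_len(d0[2]), , drop = FALSE]
    }
    dx <- dxp
  }
  list(dw = dw, db = db, dx = dx)
}

# 2x2 stride-2 transposed convolution (upsampling deconvolution).
deconv2x2_fwd <- function(x, w, b = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  oc <- dim(w)[4]
  xm <- matrix(x, H * W, C)
  out <- array(0, c(2L * H, 2L * W, oc))
  for (a in 1:2) for (bb in 1:2) {
    wm <- matrix(w[a, bb, , ], C, oc)
    out[2L * seq_len(H) - 2L + a, 2L * seq_len(W) - 2L + bb, ] <-
      array(xm %*% wm, c(H, W, oc))
  }
  if (!is.null(b)) out <- out + rep(b, each = 4L * H * W)
  out
}

deconv2x2_bwd <- function(dy, x, w) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  oc <- dim(w)[4]
  xm <- matrix(x, H * W, C)
  dw <- array(0, dim(w))
  dxm <- matrix(0, H * W, C)
  for (a in 1:2) for (bb in 1:2) {
    dym <- matrix(dy[2L * seq_len(H) - 2L + a, 2L * seq_len(W) - 2L + bb, ],
                  H * W, oc)
    dw[a, bb, , ] <- crossprod(xm, dym)
    dxm <- dxm + tcrossprod(dym, matrix(w[a, bb, , ], C, oc))
  }
  db <- colSums(matrix(dy, ncol = oc))
  list(dw = dw, db = db, dx = array(dxm, d))
}

# 2x2 stride-2 max pooling; odd trailing row/col is dropped after -Inf padding
# to an even size (feature pyramids in this package are padded to multiples
# of 32 upstream, so this is a degenerate-input guard).
max_pool2 <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L == 1L || d[2] %% 2L == 1L) {
    xp <- array(-Inf, c(d[1] + d[1] %% 2L, d[2] + d[2] %% 2L, d[3]))
    xp[seq_len(d[1]), seq_len(d[2]), ] <- x
    x <- xp
    d <- dim(x)
  }
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  pmax(x[io, jo, , drop = FALSE], x[io + 1L, jo, , drop = FALSE],
       x[io, jo + 1L, , drop = FALSE], x[io + 1L, jo + 1L, , drop = FALSE])
}

# Nearest-neighbour upsampling by an integer factor.
upsample_nearest <- function(x, factor) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = factor), rep(seq_len(d[2]), each = factor), ,
    drop = FALSE]
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

leaky_relu <- function(x, slope = 0.1) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

gelu <- function(x) x * stats::pnorm(x)

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1L, max))
  m / rowSums(m)
}

# Layer normalization over the channel (last) dimension of a token matrix
# [N, C]; biased variance, eps 1e-5 (the transformer convention).
layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  sweep(xc / sqrt(v + eps), 2L, g, `*`) + rep(b, each = nrow(x))
}

# Inference-mode batch normalization on a c(H, W, C) map.
batch_norm_map <- function(x, bn, eps = 1e-5) {
  d <- dim(x)
  scale <- bn$g / sqrt(bn$rv + eps)
  shift <- bn$b - bn$rm * scale
  x * rep(scale, each = d[1] * d[2]) + rep(shift, each = d[1] * d[2])
}

## ---- parameter containers ---------------------------------------------

new_layer <- function(kind, dims, cfg = list(), buffers = NULL) {
  structure(list(kind = kind, dims = dims, cfg = cfg,
                 params = NULL, buffers = buffers),
            class = "bs_layer")
}

layer_conv2d <- function(in_ch, out_ch, k, stride = 1L,
                         pad = (k - 1L) %/% 2L, bias = TRUE) {
  dims <- list(w = c(k, k, in_ch, out_ch))
  if (bias) dims$b <- out_ch
  new_layer("conv2d", dims, cfg = list(stride = stride, pad = pad))
}

layer_deconv2x2 <- function(in_ch, out_ch, bias = TRUE) {
  dims <- list(w = c(2L, 2L, in_ch, out_ch))
  if (bias) dims$b <- out_ch
  new_layer("deconv2x2", dims)
}

layer_linear <- function(in_f, out_f, bias = TRUE) {
  dims <- list(w = c(in_f, out_f))
  if (bias) dims$b <- out_f
  new_layer("linear", dims)
}

layer_layernorm <- function(ch) new_layer("layernorm", list(g = ch, b = ch))

layer_batchnorm <- function(ch)
  new_layer("batchnorm", list(g = ch, b = ch),
            buffers = list(rm = rep(0, ch), rv = rep(1, ch)))

# Free parameter tensor (e.g. attention relative-position bias table).
layer_param <- function(name, dim) {
  d <- list()
  d[[name]] <- dim
  new_layer("param", d)
}

is_layer <- function(x) inherits(x, "bs_layer")

#' Count trainable parameters of a module tree
#'
#' Recurses over nested lists of layers; batch-norm running statistics are
#' buffers and are not counted.
#'
#' @param x a layer or nested list of layers.
#' @return integer-valued numeric count.
#' @export
n_params <- function(x) {
  if (is_layer(x)) return(sum(vapply(x$dims, prod, numeric(1))))
  if (is.list(x)) return(sum(vapply(x, n_params, numeric(1))))
  0
}

# Materialize parameter arrays in place (by value: returns the filled tree).
# Linear / attention tables: N(0, 0.02); convolutions: He-normal; norms:
# gamma = 1, beta = 0; biases zero.
init_module <- function(x) {
  if (is_layer(x)) {
    x$params <- lapply(names(x$dims), function(nm) {
      d <- x$dims[[nm]]
      n <- prod(d)
      val <- switch(x$kind,
        conv2d = ,
        deconv2x2 = {
          if (nm == "w") {
            fan_in <- prod(d[-length(d)])
            array(stats::rnorm(n, sd = sqrt(2 / fan_in)), d)
          } else numeric(d)
        },
        linear = if (nm == "w") array(stats::rnorm(n, sd = 0.02), d)
                 else numeric(d),
        layernorm = ,
        batchnorm = if (nm == "g") rep(1, d) else numeric(d),
        param = array(stats::rnorm(n, sd = 0.02), d))
      val
    })
    names(x$params) <- names(x$dims)
    return(x)
  }
  if (is.list(x)) return(lapply(x, init_module))
  x
}

# Convenience accessors.
lw <- function(l) l$params$w
lb <- function(l) l$params$b
lbn <- function(l) list(g = l$params$g, b = l$params$b,
                        rm = l$buffers$rm, rv = l$buffers$rv)

conv_layer_fwd <- function(l, x, cache = FALSE)
  conv2d_fwd(x, lw(l), lb(l), stride = l$cfg$stride, pad = l$cfg$pad,
             cache = cache)

linear_fwd <- function(l, x) {
  y <- x %*% lw(l)
  if (!is.null(lb(l))) y <- sweep(y, 2L, lb(l), `+`)
  y
}

ln_fwd <- function(l, x) layer_norm(x, l$params$g, l$params$b)

# conv + BN + leaky-ReLU block used throughout the ASFF neck (the ASFF
# reference recipe; the leaky slope keeps fusion-logit gradients alive).
cbr_block <- function(in_ch, out_ch, k, stride = 1L)
  list(conv = layer_conv2d(in_ch, out_ch, k, stride = stride, bias = FALSE),
       bn = layer_batchnorm(out_ch))

cbr_fwd <- function(blk, x)
  leaky_relu(batch_norm_map(conv_layer_fwd(blk$conv, x), lbn(blk$bn)))

## ---- flat parameter get/set for optimizers ----------------------------

# Flatten all parameters of a module tree into a named list of arrays,
# in a stable depth-first order.
flatten_params <- function(x, prefix = "") {
  if (is_layer(x)) {
    out <- x$params
    if (length(out)) names(out) <- paste0(prefix, ".", names(out))
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    out <- list()
    for (i in seq_along(x))
      out <- c(out, flatten_params(x[[i]], paste0(prefix, ".", nms[i])))
    return(out)
  }
  list()
}

# Write a flat parameter list (same order/names as flatten_params) back.
unflatten_params <- function(x, flat, prefix = "") {
  if (is_layer(x)) {
    for (nm in names(x$params)) {
      key <- paste0(prefix, ".", nm)
      if (!is.null(flat[[key]])) x$params[[nm]] <- flat[[key]]
    }
    return(x)
  }
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (i in seq_along(x))
      x[[i]] <- unflatten_params(x[[i]], flat, paste0(prefix, ".", nms[i]))
    return(x)
  }
  x
}

## ---- AdamW -------------------------------------------------------------

adamw_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.05) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, wd = weight_decay,
       t = 0L,
       m = lapply(params, function(p) array(0, dim(as.array(p)))),
       v = lapply(params, function(p) array(0, dim(as.array(p)))))
}

# One AdamW step; decay is applied to matrices/arrays ("weights"), not to
# vectors (biases, norm scales), following the Swin detection convention.
adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    upd <- mhat / (sqrt(vhat) + opt$eps)
    if (!is.null(dim(params[[nm]])) && length(dim(params[[nm]])) >= 2L)
      upd <- upd + opt$wd * params[[nm]]
    params[[nm]] <- params[[nm]] - opt$lr * upd
  }
  list(opt = opt, params = params)
}
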
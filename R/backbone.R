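# Swin-Transformer-Tiny backbone: a 4-stage hierarchical transformer with
# windowed multi-head self-attention, producing the feature pyramid C2-C5 at
# strides 4, 8, 16, 32 with channel widths C, 2C, 4C, 8C (C = 96 for Tiny).
#
# Each pair of blocks applies
#   Z^ = W-MSA(LN(Z_prev)) + Z_prev ;  Z = MLP(LN(Z^)) + Z^
# followed by the shifted-window variant (SW-MSA with cyclic shift and a
# cross-window attention mask), so stage depths must be even.

#' Construct a Swin backbone
#'
#' Defaults are the published Swin-Tiny configuration: embed dim 96, depths
#' (2, 2, 6, 2), heads (3, 6, 12, 24), window 7, MLP ratio 4. Smaller
#' configurations are used for desk-scale experiments.
#'
#' @param embed_dim stage-1 channel width C.
#' @param depths even block counts per stage.
#' @param num_heads attention heads per stage; must divide the stage width.
#' @param window_size attention window side in tokens.
#' @param mlp_ratio MLP hidden expansion.
#' @param seed seed for parameter initialization (`NULL` leaves parameters
#'   unmaterialized, e.g. for parameter counting).
#' @return object of class `swin_backbone`.
#' @export
swin_backbone <- function(embed_dim = 96L, depths = c(2L, 2L, 6L, 2L),
                          num_heads = c(3L, 6L, 12L, 24L), window_size = 7L,
                          mlp_ratio = 4, seed = 0L) {
  if (any(depths %% 2L != 0L))
    stop("swin_backbone: stage depths must be even (W-MSA/SW-MSA pairs)")
  dims <- embed_dim * c(1L, 2L, 4L, 8L)
  if (any(dims %% num_heads != 0L))
    stop("swin_backbone: num_heads must divide the stage widths")
  ws <- as.integer(window_size)
  mk_block <- function(D, nh) list(
    norm1 = layer_layernorm(D),
    qkv = layer_linear(D, 3L * D),
    rel_bias = layer_param("table", c((2L * ws - 1L)^2, nh)),
    proj = layer_linear(D, D),
    norm2 = layer_layernorm(D),
    fc1 = layer_linear(D, as.integer(mlp_ratio * D)),
    fc2 = layer_linear(as.integer(mlp_ratio * D), D))
  stages <- lapply(1:4, function(s) {
    blocks <- lapply(seq_len(depths[s]), function(i) mk_block(dims[s],
                                                              num_heads[s]))
    down <- if (s < 4L)
      list(norm = layer_layernorm(4L * dims[s]),
           reduction = layer_linear(4L * dims[s], 2L * dims[s], bias = FALSE))
    list(blocks = blocks, downsample = down)
  })
  bb <- list(cfg = list(embed_dim = as.integer(embed_dim),
                        depths = as.integer(depths),
                        num_heads = as.integer(num_heads),
                        window_size = ws, mlp_ratio = mlp_ratio,
                        dims = as.integer(dims)),
             patch_embed = list(conv = layer_conv2d(3L, embed_dim, 4L,
                                                    stride = 4L, pad = 0L),
                                norm = layer_layernorm(embed_dim)),
             stages = stages,
             out_norms = lapply(dims, layer_layernorm))
  class(bb) <- "swin_backbone"
  if (!is.null(seed)) bb <- with_seed(seed, init_module_keep_class(bb))
  bb
}

# init_module strips nothing but loses nothing either; keep S3 class through it.
init_module_keep_class <- function(x) {
  cl <- class(x)
  y <- init_module(unclass(x))
  class(y) <- cl
  y
}

# ImageNet channel normalization; input 0-255 H x W x 3.
normalize_image <- function(img) {
  mean <- c(0.485, 0.456, 0.406); sd <- c(0.229, 0.224, 0.225)
  d <- dim(img)
  (img / 255 - rep(mean, each = d[1] * d[2])) / rep(sd, each = d[1] * d[2])
}

# Zero-pad bottom/right to multiples of m (preserves the top-left origin).
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  H2 <- ceiling(d[1] / m) * m
  W2 <- ceiling(d[2] / m) * m
  if (H2 == d[1] && W2 == d[2]) return(x)
  xp <- array(0, c(H2, W2, d[3]))
  xp[seq_len(d[1]), seq_len(d[2]), ] <- x
  xp
}

#' Patch partition and linear embedding
#'
#' Splits the image into non-overlapping 4x4 patches and linearly projects
#' each 4x4x3 patch (48 values) to the embedding width, followed by layer
#' normalization.
#'
#' @param bb a `swin_backbone`.
#' @param img normalized H x W x 3 array with H, W divisible by 4.
#' @return token map array H/4 x W/4 x C.
#' @export
patch_partition_embed <- function(bb, img) {
  d <- dim(img)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("patch_partition_embed: image size must be a multiple of 4")
  t <- conv_layer_fwd(bb$patch_embed$conv, img)
  dt <- dim(t)
  tok <- matrix(t, dt[1] * dt[2], dt[3])
  array(ln_fwd(bb$patch_embed$norm, tok), dt)
}

# Relative-position-bias pair index for an effective window of side w within
# a table built for side ws (w <= ws): M^2 indices into the table rows.
rel_pos_index <- function(w, ws) {
  coords <- expand.grid(r = seq_len(w) - 1L, c = seq_len(w) - 1L)
  dr <- outer(coords$r, coords$r, `-`) + (ws - 1L)
  dc <- outer(coords$c, coords$c, `-`) + (ws - 1L)
  dr * (2L * ws - 1L) + dc + 1L
}

# Shifted-window attention mask region ids (the three-slice partition of the
# rolled grid); windows mixing region ids get -Inf attention between them.
shift_region_ids <- function(Hp, Wp, w, shift) {
  seg <- function(n) {
    id <- integer(n)
    id[seq_len(n - w)] <- 0L
    if (w - shift > 0) id[(n - w + 1L):(n - shift)] <- 1L
    id[(n - shift + 1L):n] <- 2L
    id
  }
  outer(seg(Hp), seg(Wp), function(a, b) 3L * a + b)
}

#' One Swin transformer block
#'
#' Applies windowed (or shifted-window) multi-head self-attention with
#' relative position bias and a 2-layer GELU MLP, each with pre-norm and a
#' residual connection. The token grid is padded to window multiples
#' internally; a window larger than the grid degrades to a single grid-sized
#' window.
#'
#' @param x token map array H x W x C.
#' @param block block parameter list (from a `swin_backbone` stage).
#' @param num_heads attention heads.
#' @param window_size window side.
#' @param shifted use the shifted-window variant?
#' @return token map array of the same shape.
#' @export
swin_block <- function(x, block, num_heads, window_size, shifted = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  ws0 <- as.integer(window_size)
  w <- min(ws0, H, W)
  shift <- if (shifted && (H > w || W > w)) w %/% 2L else 0L
  xp <- pad_to_multiple(x, w)
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]

  tok <- matrix(xp, Hp * Wp, C)
  h <- ln_fwd(block$norm1, tok)
  hmap <- array(h, c(Hp, Wp, C))
  if (shift > 0L)
    hmap <- hmap[c((shift + 1L):Hp, seq_len(shift)),
                 c((shift + 1L):Wp, seq_len(shift)), , drop = FALSE]

  qkv <- linear_fwd(block$qkv, matrix(hmap, Hp * Wp, C))
  dh <- C %/% num_heads
  M <- w * w
  ridx <- rel_pos_index(w, ws0)
  bias_tab <- block$rel_bias$params$table
  ids <- if (shift > 0L) shift_region_ids(Hp, Wp, w, shift) else NULL

  out <- matrix(0, Hp * Wp, C)
  nwh <- Hp %/% w; nww <- Wp %/% w
  for (bi in seq_len(nwh)) for (bj in seq_len(nww)) {
    rows <- (bi - 1L) * w + seq_len(w)
    cols <- (bj - 1L) * w + seq_len(w)
    lin <- as.vector(outer(rows, (cols - 1L) * Hp, `+`))
    mask <- NULL
    if (!is.null(ids)) {
      wid <- as.vector(ids[rows, cols])
      if (length(unique(wid)) > 1L)
        mask <- ifelse(outer(wid, wid, `!=`), -1e9, 0)
    }
    for (hd in seq_len(num_heads)) {
      off <- (hd - 1L) * dh
      Q <- qkv[lin, off + seq_len(dh), drop = FALSE] / sqrt(dh)
      K <- qkv[lin, C + off + seq_len(dh), drop = FALSE]
      V <- qkv[lin, 2L * C + off + seq_len(dh), drop = FALSE]
      att <- tcrossprod(Q, K) + matrix(bias_tab[ridx, hd], M, M)
      if (!is.null(mask)) att <- att + mask
      out[lin, off + seq_len(dh)] <- softmax_rows(att) %*% V
    }
  }
  out <- linear_fwd(block$proj, out)
  omap <- array(out, c(Hp, Wp, C))
  if (shift > 0L)
    omap <- omap[c((Hp - shift + 1L):Hp, seq_len(Hp - shift)),
                 c((Wp - shift + 1L):Wp, seq_len(Wp - shift)), ,
                 drop = FALSE]
  x <- x + omap[seq_len(H), seq_len(W), , drop = FALSE]

  tok <- matrix(x, H * W, C)
  m <- gelu(linear_fwd(block$fc1, ln_fwd(block$norm2, tok)))
  tok <- tok + linear_fwd(block$fc2, m)
  array(tok, d)
}

# Patch merging: concatenate each 2x2 token neighbourhood (4C), layer norm,
# linear reduction to 2C. Odd grids are zero-padded bottom/right.
patch_merging <- function(x, down) {
  x <- pad_to_multiple(x, 2L)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  io <- seq(1L, H, by = 2L); jo <- seq(1L, W, by = 2L)
  cat4 <- cbind(matrix(x[io, jo, ], length(io) * length(jo), C),
                matrix(x[io + 1L, jo, ], length(io) * length(jo), C),
                matrix(x[io, jo + 1L, ], length(io) * length(jo), C),
                matrix(x[io + 1L, jo + 1L, ], length(io) * length(jo), C))
  red <- linear_fwd(down$reduction, ln_fwd(down$norm, cat4))
  array(red, c(length(io), length(jo), 2L * C))
}

#' Extract the 4-level feature pyramid
#'
#' Runs the full backbone: patch embedding, the four stages of Swin blocks
#' with patch merging in between, and a per-stage output layer norm, giving
#' C2-C5 at strides 4, 8, 16, 32.
#'
#' @param bb a `swin_backbone` with materialized parameters.
#' @param image H x W x 3 array in 0-255 (raw) or pre-normalized when
#'   `normalize = FALSE`.
#' @param normalize apply channel normalization?
#' @return list of 4 arrays (C2, C3, C4, C5) with widths C, 2C, 4C, 8C; the
#'   input is zero-padded bottom/right to a multiple of 32 first.
#' @export
extract_pyramid <- function(bb, image, normalize = TRUE) {
  d <- dim(image)
  if (d[1] < 32L || d[2] < 32L)
    stop("extract_pyramid: image must be at least 32 px on a side")
  if (normalize) image <- normalize_image(image)
  image <- pad_to_multiple(image, 32L)
  x <- patch_partition_embed(bb, image)
  cfg <- bb$cfg
  out <- vector("list", 4L)
  for (s in 1:4) {
    blocks <- bb$stages[[s]]$blocks
    for (i in seq_along(blocks))
      x <- swin_block(x, blocks[[i]], cfg$num_heads[s], cfg$window_size,
                      shifted = (i %% 2L == 0L))
    dx <- dim(x)
    nt <- ln_fwd(bb$out_norms[[s]], matrix(x, dx[1] * dx[2], dx[3]))
    out[[s]] <- array(nt, dx)
    if (s < 4L) x <- patch_merging(x, bb$stages[[s]]$downsample)
  }
  names(out) <- c("c2", "c3", "c4", "c5")
  out
}
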
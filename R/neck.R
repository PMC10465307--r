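# Adaptively spatial feature fusion (ASFF) neck, extended to the 4 backbone
# levels: every level is resampled to every target resolution and fused with
# per-location softmax weights
#   Y^l_ij = a^l_ij X^{1->l}_ij + b^l_ij X^{2->l}_ij
#          + g^l_ij X^{3->l}_ij + d^l_ij X^{4->l}_ij,
# the four weights being a softmax over per-location logits computed by 1x1
# convolutions on the resized maps. A plain FPN neck is provided as the
# ablation baseline.

#' Construct an ASFF neck
#'
#' Resampling operators per (source, target) pair: same level, a 1x1
#' convolution to `out_channels`; up-sampling, 1x1 convolution then nearest
#' interpolation by 2/4/8; down-sampling by 1/2, a stride-2 3x3 convolution;
#' by 1/4 (1/8), one (two) max-pooling operation(s) before the stride-2
#' convolution. Each convolution is followed by batch norm and ReLU. Fusion
#' logits: each resized map is compressed to `compress` channels by a 1x1
#' convolution, the four embeddings are concatenated, and a final 1x1
#' convolution yields the 4 logit maps; a 3x3 convolution expands each fused
#' map. A stride-64 extra level for proposals is appended by max-pooling the
#' coarsest output.
#'
#' @param in_channels backbone channel widths C2-C5.
#' @param out_channels fused map width (256).
#' @param compress width of the per-source weight embedding (16, the ASFF
#'   reference default for this model family).
#' @param seed parameter init seed (`NULL` leaves parameters empty).
#' @return object of class `asff_neck`.
#' @export
asff_neck <- function(in_channels = c(96L, 192L, 384L, 768L),
                      out_channels = 256L, compress = 16L, seed = 0L) {
  oc <- as.integer(out_channels)
  levels <- lapply(1:4, function(l) {
    resample <- lapply(1:4, function(n) {
      if (n == l) list(op = "same", cbr = cbr_block(in_channels[n], oc, 1L))
      else if (n > l) list(op = "up", factor = 2L^(n - l),
                           cbr = cbr_block(in_channels[n], oc, 1L))
      else list(op = "down", pools = l - n - 1L,
                cbr = cbr_block(in_channels[n], oc, 3L, stride = 2L))
    })
    list(resample = resample,
         weight_embed = lapply(1:4, function(n) cbr_block(oc, compress, 1L)),
         weight_logits = layer_conv2d(4L * compress, 4L, 1L, bias = TRUE),
         expand = cbr_block(oc, oc, 3L))
  })
  neck <- structure(list(cfg = list(in_channels = as.integer(in_channels),
                                    out_channels = oc,
                                    compress = as.integer(compress)),
                         levels = levels),
                    class = "asff_neck")
  if (!is.null(seed)) neck <- with_seed(seed, init_module_keep_class(neck))
  neck
}

crop_or_pad_to <- function(x, shape) {
  d <- dim(x)
  if (d[1] == shape[1] && d[2] == shape[2]) return(x)
  out <- array(0, c(shape[1], shape[2], d[3]))
  r <- seq_len(min(d[1], shape[1])); cc <- seq_len(min(d[2], shape[2]))
  out[r, cc, ] <- x[r, cc, , drop = FALSE]
  out
}

#' Resample one backbone level to a target level's resolution
#'
#' @param neck an `asff_neck`.
#' @param x feature array at `src_level`'s resolution.
#' @param src_level,dst_level levels in 1..4 (stride 4 * 2^(level-1)).
#' @param dst_shape optional c(H, W) of the destination level; output is
#'   cropped/padded to it exactly (sizes that are multiples of 8 never need
#'   this).
#' @return array at the destination resolution with `out_channels` channels.
#' @export
resample_to_level <- function(neck, x, src_level, dst_level,
                              dst_shape = NULL) {
  if (!src_level %in% 1:4 || !dst_level %in% 1:4)
    stop("resample_to_level: levels must be in 1..4")
  rs <- neck$levels[[dst_level]]$resample[[src_level]]
  out <- switch(rs$op,
    same = cbr_fwd(rs$cbr, x),
    up = upsample_nearest(cbr_fwd(rs$cbr, x), rs$factor),
    down = {
      for (i in seq_len(rs$pools)) x <- max_pool2(x)
      cbr_fwd(rs$cbr, x)
    })
  if (!is.null(dst_shape)) out <- crop_or_pad_to(out, dst_shape)
  out
}

# Per-location fusion weights at level l from the resized maps: softmax over
# the 4 logit maps. Returns list(weights = H x W x 4, logits = H x W x 4).
fusion_weights <- function(neck, l, resized) {
  lv <- neck$levels[[l]]
  emb <- lapply(1:4, function(n) cbr_fwd(lv$weight_embed[[n]], resized[[n]]))
  cat <- array(unlist(emb), c(dim(emb[[1]])[1], dim(emb[[1]])[2],
                              4L * dim(emb[[1]])[3]))
  logits <- conv_layer_fwd(lv$weight_logits, cat)
  d <- dim(logits)
  w <- softmax_rows(matrix(logits, d[1] * d[2], 4L))
  list(weights = array(w, d), logits = logits)
}

#' Fuse four resized maps with per-location weights
#'
#' @param resized list of 4 arrays of identical shape.
#' @param weights H x W x 4 array of per-location fusion weights; every
#'   location must sum to 1 within 1e-5.
#' @return the fused map Y^l.
#' @export
fuse_level <- function(resized, weights) {
  d <- dim(resized[[1]])
  for (n in 2:4)
    if (!identical(dim(resized[[n]]), d))
      stop("fuse_level: resized maps must share one shape")
  wsum <- apply(weights, c(1, 2), sum)
  if (max(abs(wsum - 1)) > 1e-5)
    stop("fuse_level: weights must sum to 1 at every location")
  out <- array(0, d)
  for (n in 1:4) {
    wn <- array(rep(weights[, , n], d[3]), d)
    out <- out + wn * resized[[n]]
  }
  out
}

#' Run the ASFF neck over a backbone pyramid
#'
#' @param neck an `asff_neck` with materialized parameters.
#' @param stages list of 4 backbone maps C2-C5.
#' @param extra_level append the stride-64 proposal level (max-pooled from
#'   the coarsest fused map)?
#' @return list of fused maps `y1..y4` (+ `p_extra`), all `out_channels`
#'   wide; a `fusion_weights` attribute holds the 4 per-level weight arrays.
#' @export
asff_forward <- function(neck, stages, extra_level = TRUE) {
  out <- vector("list", 4L)
  wlist <- vector("list", 4L)
  for (l in 1:4) {
    dst_shape <- dim(stages[[l]])[1:2]
    resized <- lapply(1:4, function(n)
      resample_to_level(neck, stages[[n]], n, l, dst_shape = dst_shape))
    fw <- fusion_weights(neck, l, resized)
    y <- fuse_level(resized, fw$weights)
    out[[l]] <- cbr_fwd(neck$levels[[l]]$expand, y)
    wlist[[l]] <- fw$weights
  }
  names(out) <- paste0("y", 1:4)
  if (extra_level) out$p_extra <- max_pool2(out$y4)
  attr(out, "fusion_weights") <- wlist
  out
}

#' Construct a plain FPN neck (ablation baseline)
#'
#' Lateral 1x1 convolutions to `out_channels`, top-down nearest up-sampling
#' with element-wise addition, 3x3 output convolutions, and a max-pooled
#' extra proposal level.
#'
#' @inheritParams asff_neck
#' @return object of class `fpn_neck`.
#' @export
fpn_neck <- function(in_channels = c(96L, 192L, 384L, 768L),
                     out_channels = 256L, seed = 0L) {
  oc <- as.integer(out_channels)
  neck <- structure(list(
    cfg = list(in_channels = as.integer(in_channels), out_channels = oc),
    lateral = lapply(in_channels, function(ic) layer_conv2d(ic, oc, 1L)),
    output = lapply(1:4, function(i) layer_conv2d(oc, oc, 3L))),
    class = "fpn_neck")
  if (!is.null(seed)) neck <- with_seed(seed, init_module_keep_class(neck))
  neck
}

#' @rdname fpn_neck
#' @param neck an `fpn_neck`.
#' @param stages backbone maps C2-C5.
#' @param extra_level append the stride-64 level?
#' @export
fpn_forward <- function(neck, stages, extra_level = TRUE) {
  lat <- lapply(1:4, function(i) conv_layer_fwd(neck$lateral[[i]],
                                                stages[[i]]))
  for (l in 3:1) {
    up <- upsample_nearest(lat[[l + 1L]], 2L)
    lat[[l]] <- lat[[l]] + crop_or_pad_to(up, dim(lat[[l]])[1:2])
  }
  out <- lapply(1:4, function(i) conv_layer_fwd(neck$output[[i]], lat[[i]]))
  names(out) <- paste0("y", 1:4)
  if (extra_level) out$p_extra <- max_pool2(out$y4)
  out
}

# Generic neck dispatch used by the assembled model.
neck_forward <- function(neck, stages, extra_level = TRUE) {
  if (inherits(neck, "asff_neck")) asff_forward(neck, stages, extra_level)
  else fpn_forward(neck, stages, extra_level)
}
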
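# Two-stage detection heads on the fused pyramid: a region proposal network
# (shared 3x3 convolution, per-anchor objectness and box-delta 1x1
# convolutions), ROI-aligned box classification/regression (two 1024-wide
# fully connected layers), and a fully convolutional mask head (four 3x3
# convolutions, a 2x2 up-convolution and a 1x1 logit layer predicting a
# 28x28 mask per detection).

rpn_head_new <- function(channels = 256L, n_anchors = 3L) {
  list(conv = layer_conv2d(channels, channels, 3L),
       cls = layer_conv2d(channels, n_anchors, 1L),
       reg = layer_conv2d(channels, 4L * n_anchors, 1L))
}

box_head_new <- function(channels = 256L, roi_size = 7L, fc_dim = 1024L,
                         n_classes = 1L) {
  list(fc1 = layer_linear(channels * roi_size^2, fc_dim),
       fc2 = layer_linear(fc_dim, fc_dim),
       cls = layer_linear(fc_dim, n_classes + 1L),
       reg = layer_linear(fc_dim, 4L * n_classes))
}

mask_head_new <- function(channels = 256L, n_convs = 4L, n_classes = 1L) {
  list(convs = lapply(seq_len(n_convs),
                      function(i) layer_conv2d(channels, channels, 3L)),
       deconv = layer_deconv2x2(channels, channels),
       logits = layer_conv2d(channels, n_classes, 1L))
}

# RPN forward on one pyramid level; returns logits, deltas and caches for
# the backward pass.
rpn_level_fwd <- function(head, feat, cache = FALSE) {
  c1 <- conv_layer_fwd(head$conv, feat, cache = cache)
  h <- relu(if (cache) c1$out else c1)
  cl <- conv_layer_fwd(head$cls, h, cache = cache)
  rg <- conv_layer_fwd(head$reg, h, cache = cache)
  if (!cache) return(list(cls = cl, reg = rg))
  list(cls = cl$out, reg = rg$out,
       cache = list(conv = c1$cache, pre_relu = c1$out, hidden = h,
                    cls = cl$cache, reg = rg$cache))
}

# Flatten level predictions to the anchor ordering of generate_anchors()
# (ratio fastest, then row, then column).
flatten_rpn_level <- function(cls, reg, n_anchors) {
  scores <- as.vector(aperm(cls, c(3, 1, 2)))
  deltas <- t(matrix(as.vector(aperm(reg, c(3, 1, 2))), nrow = 4L))
  list(scores = scores, deltas = deltas)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Generate scored region proposals
#'
#' Per-level objectness and box-delta heads over the anchor grid, top-k
#' pre-selection per level, delta decoding, clipping to the image, and
#' candidate filtering by hard NMS or Gaussian Soft-NMS.
#'
#' @param pyramid list of fused maps (one per anchor stride).
#' @param rpn RPN head parameter list.
#' @param anchors_cfg an [anchor_config()].
#' @param image_shape c(H, W) of the (padded) input image.
#' @param mode "soft" or "hard" candidate filtering.
#' @param pre_topk per-level candidates kept before filtering.
#' @param post_topk proposals kept after filtering.
#' @param nms_sigma,nms_iou,score_thresh filtering parameters.
#' @param min_size minimum proposal side in pixels.
#' @return data.frame x1, y1, x2, y2, score (all boxes within image bounds).
#' @export
rpn_propose <- function(pyramid, rpn, anchors_cfg, image_shape,
                        mode = c("soft", "hard"), pre_topk = 1000L,
                        post_topk = 300L, nms_sigma = 0.5, nms_iou = 0.7,
                        score_thresh = 0.05, min_size = 1) {
  mode <- match.arg(mode)
  n_anchors <- length(anchors_cfg$ratios)
  shapes <- lapply(pyramid, function(p) dim(p)[1:2])
  anchors <- generate_anchors(anchors_cfg, shapes)
  all_boxes <- list(); all_scores <- list()
  for (l in seq_along(pyramid)) {
    out <- rpn_level_fwd(rpn, pyramid[[l]])
    fl <- flatten_rpn_level(out$cls, out$reg, n_anchors)
    sc <- sigmoid(fl$scores)
    take <- utils::head(order(-sc), pre_topk)
    boxes <- bbox_decode(anchors[[l]][take, , drop = FALSE],
                         fl$deltas[take, , drop = FALSE])
    boxes <- clip_boxes(boxes, image_shape[1], image_shape[2])
    ok <- (boxes[, 3] - boxes[, 1]) >= min_size &
          (boxes[, 4] - boxes[, 2]) >= min_size
    all_boxes[[l]] <- boxes[ok, , drop = FALSE]
    all_scores[[l]] <- sc[take][ok]
  }
  boxes <- do.call(rbind, all_boxes)
  scores <- unlist(all_scores)
  if (!length(scores))
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), score = numeric()))
  dets <- data.frame(boxes, score = scores)
  names(dets) <- c("x1", "y1", "x2", "y2", "score")
  kept <- if (mode == "soft")
    soft_nms(dets, sigma = nms_sigma, score_thresh = score_thresh)
  else hard_nms(dets, iou_thresh = nms_iou)
  utils::head(kept[order(-kept$score), , drop = FALSE], post_topk)
}

# Bilinear sample of a [H, W, C] map at points (x, y) in 0-based continuous
# pixel coordinates (pixel centres at integer + 0.5); zero outside.
bilinear_sample <- function(feat, x, y) {
  d <- dim(feat); H <- d[1]; W <- d[2]; C <- d[3]
  fx <- x - 0.5; fy <- y - 0.5
  x0 <- floor(fx); y0 <- floor(fy)
  wx <- fx - x0; wy <- fy - y0
  fm <- matrix(feat, H * W, C)
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (W - 1) & yi >= 0 & yi <= (H - 1)
    idx <- pmin(pmax(yi, 0), H - 1) + 1L + pmin(pmax(xi, 0), W - 1) * H
    v <- fm[idx, , drop = FALSE]
    v[!ok, ] <- 0
    v
  }
  v00 <- gather(x0, y0); v10 <- gather(x0 + 1, y0)
  v01 <- gather(x0, y0 + 1); v11 <- gather(x0 + 1, y0 + 1)
  (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
}

#' ROI Align feature pooling
#'
#' Pools a fixed `out_size` x `out_size` grid per box by averaging `sampling`
#' x `sampling` bilinear samples per bin (aligned corners convention).
#'
#' @param feat feature array H x W x C at one pyramid level.
#' @param boxes n x 4 corner boxes in image coordinates.
#' @param out_size output grid side.
#' @param spatial_scale feature pixels per image pixel (1 / stride).
#' @param sampling samples per bin side.
#' @return array n x out_size x out_size x C... returned as a list of
#'   out_size x out_size x C arrays, one per box.
#' @export
roi_align <- function(feat, boxes, out_size = 7L, spatial_scale = 1,
                      sampling = 2L) {
  boxes <- as_box_matrix(boxes)
  lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ] * spatial_scale
    bw <- max(b[3] - b[1], 1e-3); bh <- max(b[4] - b[2], 1e-3)
    step_x <- bw / (out_size * sampling)
    step_y <- bh / (out_size * sampling)
    gx <- b[1] + (seq_len(out_size * sampling) - 0.5) * step_x
    gy <- b[2] + (seq_len(out_size * sampling) - 0.5) * step_y
    pts_x <- rep(gx, each = out_size * sampling)
    pts_y <- rep(gy, times = out_size * sampling)
    v <- bilinear_sample(feat, pts_x, pts_y)   # [(os*s)^2, C], y fastest
    C <- ncol(v)
    a <- array(v, c(out_size * sampling, out_size * sampling, C))
    # average sampling x sampling blocks
    out <- array(0, c(out_size, out_size, C))
    for (si in seq_len(sampling)) for (sj in seq_len(sampling)) {
      out <- out + a[seq(si, by = sampling, length.out = out_size),
                     seq(sj, by = sampling, length.out = out_size), ,
                     drop = FALSE]
    }
    out / sampling^2
  })
}

# Pyramid level for each ROI (the standard FPN assignment rule with finest
# scale 56): level = clamp(floor(log2(sqrt(area) / 56)), 0, 3) + 1.
roi_levels <- function(boxes, n_levels = 4L) {
  s <- sqrt(box_area(boxes))
  lvl <- floor(log2(s / 56 + 1e-8))
  pmin(pmax(lvl, 0), n_levels - 1L) + 1L
}

box_head_fwd <- function(head, roi_feats) {
  x <- do.call(rbind, lapply(roi_feats, as.vector))
  h1 <- relu(linear_fwd(head$fc1, x))
  h2 <- relu(linear_fwd(head$fc2, h1))
  list(cls = linear_fwd(head$cls, h2), reg = linear_fwd(head$reg, h2),
       x = x, h1 = h1, h2 = h2)
}

mask_head_fwd <- function(head, roi_feat, cache = FALSE) {
  caches <- list()
  x <- roi_feat
  for (i in seq_along(head$convs)) {
    cv <- conv_layer_fwd(head$convs[[i]], x, cache = cache)
    if (cache) {
      caches[[i]] <- list(cache = cv$cache, pre = cv$out, input = x)
      x <- relu(cv$out)
    } else x <- relu(cv)
  }
  dc_in <- x
  x <- deconv2x2_fwd(x, lw(head$deconv), lb(head$deconv))
  pre_dc <- x
  x <- relu(x)
  lg_in <- x
  lg <- conv_layer_fwd(head$logits, x, cache = cache)
  if (!cache) return(list(logits = lg))
  list(logits = lg$out,
       cache = list(convs = caches, dc_in = dc_in, pre_dc = pre_dc,
                    lg_in = lg_in, lg_cache = lg$cache))
}

# Bilinear resize of a 2-D matrix to (h, w); pixel centres at k - 0.5,
# edge-clamped sampling.
resize_bilinear <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  src_y <- (seq_len(h) - 0.5) * H / h       # 0-based continuous coords
  src_x <- (seq_len(w) - 0.5) * W / w
  c0 <- function(s, n) pmin(pmax(floor(s - 0.5) + 0.5, 0.5), n - 0.5)
  y0 <- c0(src_y, H); x0 <- c0(src_x, W)
  y1 <- pmin(y0 + 1, H - 0.5); x1 <- pmin(x0 + 1, W - 0.5)
  wy <- pmin(pmax(src_y - y0, 0), 1); wx <- pmin(pmax(src_x - x0, 0), 1)
  iy0 <- as.integer(y0 + 0.5); iy1 <- as.integer(y1 + 0.5)
  ix0 <- as.integer(x0 + 0.5); ix1 <- as.integer(x1 + 0.5)
  m00 <- m[iy0, ix0, drop = FALSE]; m01 <- m[iy0, ix1, drop = FALSE]
  m10 <- m[iy1, ix0, drop = FALSE]; m11 <- m[iy1, ix1, drop = FALSE]
  WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)
  (1 - WY) * (1 - WX) * m00 + (1 - WY) * WX * m01 +
    WY * (1 - WX) * m10 + WY * WX * m11
}

# Paste a mask probability patch predicted for `box` into an H x W canvas,
# binarized at `thresh`.
paste_mask <- function(prob, box, H, W, thresh = 0.5) {
  x0 <- max(0L, floor(box[1])); x1 <- min(W, ceiling(box[3]))
  y0 <- max(0L, floor(box[2])); y1 <- min(H, ceiling(box[4]))
  out <- matrix(FALSE, H, W)
  if (x1 - x0 < 1 || y1 - y0 < 1) return(out)
  patch <- resize_bilinear(prob, y1 - y0, x1 - x0)
  out[(y0 + 1L):y1, (x0 + 1L):x1] <- patch >= thresh
  out
}

#' Detect and segment berries in one image
#'
#' Full two-stage inference: backbone pyramid, neck fusion, region
#' proposals, ROI-aligned box refinement and classification, final Soft-NMS
#' (or hard NMS) filtering, and per-detection mask prediction binarized at
#' 0.5 in image space.
#'
#' @param model an assembled model from [build_model()].
#' @param image H x W x 3 array in 0-255.
#' @param score_thresh minimum classification score kept (in \[0, 1\]).
#' @param max_dets cap on returned detections.
#' @param masks predict masks?
#' @return list with `boxes` (n x 4), `scores`, `masks` (list of H x W
#'   logical matrices, or NULL), in decreasing score order.
#' @export
detect_and_segment <- function(model, image, score_thresh = 0.5,
                               max_dets = 300L, masks = TRUE) {
  if (score_thresh < 0 || score_thresh > 1)
    stop("detect_and_segment: score_thresh must be in [0, 1]")
  H <- dim(image)[1]; W <- dim(image)[2]
  pyr <- model_pyramid(model, image)
  props <- rpn_propose(pyr, model$heads$rpn, model$anchors,
                       image_shape = c(H, W),
                       mode = if (model$cfg$soft_nms) "soft" else "hard",
                       pre_topk = model$cfg$rpn_pre_topk,
                       post_topk = model$cfg$rpn_post_topk)
  empty <- list(boxes = matrix(numeric(), 0, 4), scores = numeric(),
                masks = if (masks) list() else NULL)
  if (!nrow(props)) return(empty)
  pboxes <- as_box_matrix(props)
  lv <- roi_levels(pboxes)
  strides <- c(4, 8, 16, 32)
  feats <- vector("list", nrow(pboxes))
  for (l in sort(unique(lv))) {
    sel <- which(lv == l)
    feats[sel] <- roi_align(pyr[[l]], pboxes[sel, , drop = FALSE],
                            out_size = 7L, spatial_scale = 1 / strides[l])
  }
  bh <- box_head_fwd(model$heads$box, feats)
  prob <- softmax_rows(bh$cls)[, 2L]
  boxes <- bbox_decode(pboxes, bh$reg)
  boxes <- clip_boxes(boxes, H, W)
  keep <- which(prob >= score_thresh &
                (boxes[, 3] - boxes[, 1]) >= 1 &
                (boxes[, 4] - boxes[, 2]) >= 1)
  if (!length(keep)) return(empty)
  dets <- data.frame(boxes[keep, , drop = FALSE], score = prob[keep])
  names(dets) <- c("x1", "y1", "x2", "y2", "score")
  final <- if (model$cfg$soft_nms)
    soft_nms(dets, sigma = model$cfg$nms_sigma,
             score_thresh = min(score_thresh, 0.05))
  else hard_nms(dets, iou_thresh = 0.5)
  final <- utils::head(final[order(-final$score), , drop = FALSE], max_dets)
  fboxes <- as_box_matrix(final)
  out_masks <- NULL
  if (masks) {
    lv <- roi_levels(fboxes)
    out_masks <- vector("list", nrow(fboxes))
    for (i in seq_len(nrow(fboxes))) {
      rf <- roi_align(pyr[[lv[i]]], fboxes[i, , drop = FALSE],
                      out_size = 14L, spatial_scale = 1 / strides[lv[i]])[[1]]
      mh <- mask_head_fwd(model$heads$mask, rf)
      prob_map <- sigmoid(mh$logits[, , 1])
      out_masks[[i]] <- paste_mask(prob_map, fboxes[i, ], H, W)
    }
  }
  list(boxes = fboxes, scores = final$score, masks = out_masks)
}

#' Count berries from detections
#'
#' @param dets detection list from [detect_and_segment()] (or any list with
#'   a `scores` field).
#' @param score_thresh detections at or above this score are counted.
#' @return list of class `bunch_count` with `predicted_count` and `kept`
#'   (indices of counted detections).
#' @export
count_berries <- function(dets, score_thresh = 0.5) {
  kept <- which(dets$scores >= score_thresh)
  structure(list(predicted_count = length(kept), kept = kept),
            class = "bunch_count")
}
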
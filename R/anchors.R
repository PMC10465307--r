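# Anchor generation, dataset box statistics and candidate suppression.
#
# Anchors follow the MMDetection convention: one scale per pyramid level,
# used as a multiplier of the level stride, so that the base anchor at each
# level has area (stride * scale)^2; per-ratio shapes preserve that area.
# The berry-optimized scale is 2, giving base anchors of side
# 8, 16, 32, 64, 128 over strides 4, 8, 16, 32, 64; the COCO default is 8
# (sides 32 ... 512).

#' Anchor configuration
#'
#' @param strides pixels per pyramid level, strictly increasing.
#' @param ratios aspect ratios (width/height), positive.
#' @param scale positive multiplier of the stride: 2 is the berry-optimized
#'   setting, 8 the COCO default.
#' @return object of class `anchor_config`.
#' @export
anchor_config <- function(strides = c(4L, 8L, 16L, 32L, 64L),
                          ratios = c(0.5, 1, 2), scale = 2) {
  if (any(diff(strides) <= 0)) stop("anchor_config: strides must increase")
  if (any(ratios <= 0)) stop("anchor_config: ratios must be positive")
  if (length(scale) != 1L || scale <= 0)
    stop("anchor_config: scale must be a positive scalar")
  structure(list(strides = as.numeric(strides), ratios = as.numeric(ratios),
                 scale = as.numeric(scale)),
            class = "anchor_config")
}

# Base anchors for one level, centred at the origin: area-preserving aspect
# algebra w = sqrt(A * r), h = sqrt(A / r) with A = (stride * scale)^2.
base_anchors <- function(stride, scale, ratios) {
  A <- (stride * scale)^2
  w <- sqrt(A * ratios)
  h <- sqrt(A / ratios)
  cbind(x1 = -w / 2, y1 = -h / 2, x2 = w / 2, y2 = h / 2)
}

#' Generate tiled anchors over a feature pyramid
#'
#' Anchors are tiled at every stride step, centred on cell centres at
#' `(i + 0.5) * stride`.
#'
#' @param cfg an [anchor_config()].
#' @param level_shapes list of c(H, W) grid shapes, one per stride.
#' @return list of per-level matrices (x1, y1, x2, y2), `H * W * n_ratios`
#'   rows each, ratio index varying fastest.
#' @export
generate_anchors <- function(cfg, level_shapes) {
  if (!length(level_shapes)) stop("generate_anchors: empty level_shapes")
  if (length(level_shapes) != length(cfg$strides))
    stop("generate_anchors: need one shape per stride")
  lapply(seq_along(cfg$strides), function(l) {
    s <- cfg$strides[l]
    base <- base_anchors(s, cfg$scale, cfg$ratios)
    hw <- level_shapes[[l]]
    cx <- (seq_len(hw[2]) - 0.5) * s
    cy <- (seq_len(hw[1]) - 0.5) * s
    # cell order: row fastest (matches column-major map flattening)
    ctr <- cbind(rep(rep(cx, each = hw[1]), each = nrow(base)),
                 rep(rep(cy, times = hw[2]), each = nrow(base)))
    ab <- base[rep(seq_len(nrow(base)), times = hw[1] * hw[2]), , drop = FALSE]
    cbind(x1 = ab[, 1] + ctr[, 1], y1 = ab[, 2] + ctr[, 2],
          x2 = ab[, 3] + ctr[, 1], y2 = ab[, 4] + ctr[, 2])
  })
}

#' Box statistics of a dataset's annotations
#'
#' Computes per-annotation width, height, aspect ratio and box area (after an
#' optional training resize) together with histograms, and suggests the
#' anchor scale from {1, 2, 4, 8} whose anchor-area range is best centred on
#' the observed areas (closest log-scale midpoints).
#'
#' @param coco a COCO structure from [read_coco_dataset()] (or a compatible
#'   list with `annotations` and `images`).
#' @param resize optional c(long, short) training resize target, e.g.
#'   c(1333, 800); annotation sizes are multiplied by the per-image resize
#'   scale. `NULL` (default) keeps native scale.
#' @param strides anchor strides used for the scale suggestion.
#' @param breaks histogram bin count.
#' @return list with `stats` (data.frame width/height/aspect/area),
#'   `histograms`, and `suggested_scale`.
#' @export
dataset_box_stats <- function(coco, resize = NULL,
                              strides = c(4, 8, 16, 32, 64), breaks = 30L) {
  anns <- coco$annotations
  if (!length(anns)) stop("dataset_box_stats: no annotations")
  img_scale <- rep(1, length(coco$images))
  names(img_scale) <- vapply(coco$images, function(im) as.character(im$id),
                             character(1))
  if (!is.null(resize)) {
    for (im in coco$images) {
      s <- min(resize[2] / min(im$height, im$width),
               resize[1] / max(im$height, im$width))
      img_scale[as.character(im$id)] <- s
    }
  }
  rows <- lapply(anns, function(a) {
    s <- img_scale[as.character(a$image_id)]
    bb <- unlist(a$bbox)
    w <- bb[3] * s; h <- bb[4] * s
    data.frame(width = w, height = h, aspect = w / h, area = w * h)
  })
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  hists <- lapply(stats, function(v) graphics::hist(v, breaks = breaks,
                                                    plot = FALSE))
  cand <- c(1, 2, 4, 8)
  obs_mid <- mean(log(range(stats$area)))
  fit <- vapply(cand, function(s) {
    areas <- (strides * s)^2
    abs(mean(log(range(areas))) - obs_mid)
  }, numeric(1))
  structure(list(stats = stats, histograms = hists,
                 suggested_scale = cand[which.min(fit)]),
            class = "box_stats")
}

#' Write per-annotation box statistics to CSV
#'
#' @param stats a `box_stats` object.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_box_stats <- function(stats, path) {
  utils::write.csv(stats$stats, path, row.names = FALSE)
  invisible(path)
}

#' Gaussian Soft-NMS
#'
#' Iteratively moves the current highest-scoring box M into the kept set and
#' rescales every remaining score by the Gaussian penalty
#' `S_i <- S_i * exp(-IoU(M, b_i)^2 / sigma)`; boxes whose decayed score
#' falls below `score_thresh` are discarded. Ties on equal scores keep the
#' lower original index first.
#'
#' @param dets data.frame with columns x1, y1, x2, y2, score (or a 4-column
#'   box matrix plus `scores`).
#' @param sigma positive Gaussian width.
#' @param score_thresh discard threshold on decayed scores.
#' @param scores optional score vector when `dets` is a matrix.
#' @return data.frame x1, y1, x2, y2, score of kept boxes, in selection
#'   order, with final decayed scores; a `kept` attribute holds the original
#'   row indices.
#' @export
soft_nms <- function(dets, sigma = 0.5, score_thresh = 0.05, scores = NULL) {
  if (sigma <= 0) stop("soft_nms: sigma must be positive")
  boxes <- as_box_matrix(dets)
  if (is.null(scores)) scores <- dets$score
  n <- nrow(boxes)
  keep <- integer(0)
  kept_scores <- numeric(0)
  idx <- seq_len(n)
  s <- scores
  while (length(idx)) {
    best <- idx[order(-s[idx])[1]]          # ties: lower index first
    keep <- c(keep, best)
    kept_scores <- c(kept_scores, s[best])
    idx <- setdiff(idx, best)
    if (!length(idx)) break
    ious <- box_iou_matrix(boxes[best, , drop = FALSE],
                           boxes[idx, , drop = FALSE])[1, ]
    s[idx] <- s[idx] * exp(-(ious^2) / sigma)
    idx <- idx[s[idx] >= score_thresh]
  }
  out <- data.frame(boxes[keep, , drop = FALSE], score = kept_scores)
  names(out) <- c("x1", "y1", "x2", "y2", "score")
  rownames(out) <- NULL
  attr(out, "kept") <- keep
  out
}

#' Hard (greedy) non-maximum suppression
#'
#' Greedy max-score selection discarding boxes whose IoU with any kept box
#' exceeds `iou_thresh`; the classical ablation baseline for Soft-NMS.
#'
#' @inheritParams soft_nms
#' @param iou_thresh suppression threshold in (0, 1).
#' @return data.frame of kept rows (original scores), `kept` attribute as in
#'   [soft_nms()].
#' @export
hard_nms <- function(dets, iou_thresh = 0.7, scores = NULL) {
  if (iou_thresh <= 0 || iou_thresh >= 1)
    stop("hard_nms: iou_thresh must be in (0, 1)")
  boxes <- as_box_matrix(dets)
  if (is.null(scores)) scores <- dets$score
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    keep <- c(keep, ord[i])
    if (i < length(ord)) {
      rest <- ord[(i + 1L):length(ord)]
      ious <- box_iou_matrix(boxes[ord[i], , drop = FALSE],
                             boxes[rest, , drop = FALSE])[1, ]
      alive[(i + 1L):length(ord)][ious > iou_thresh] <- FALSE
    }
  }
  out <- data.frame(boxes[keep, , drop = FALSE], score = scores[keep])
  names(out) <- c("x1", "y1", "x2", "y2", "score")
  rownames(out) <- NULL
  attr(out, "kept") <- keep
  out
}
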
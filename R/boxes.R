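# Axis-aligned box utilities. Boxes use the corner convention
# (x1, y1, x2, y2) with x1 < x2, y1 < y2, 0-based continuous coordinates and
# exclusive-corner area (x2 - x1) * (y2 - y1), consistent with COCO tooling.

as_box_matrix <- function(boxes) {
  if (is.data.frame(boxes))
    boxes <- as.matrix(boxes[, c("x1", "y1", "x2", "y2")])
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4, byrow = TRUE)
  boxes
}

box_area <- function(boxes) {
  boxes <- as_box_matrix(boxes)
  pmax(0, boxes[, 3] - boxes[, 1]) * pmax(0, boxes[, 4] - boxes[, 2])
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as length-4 vectors (x1, y1, x2, y2).
#' @return IoU in \[0, 1\]; degenerate (zero-area) boxes give 0.
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  u <- box_area(a) + box_area(b) - inter
  if (u <= 0) return(0)
  inter / u
}

# IoU matrix between two box sets (n x 4, m x 4) -> n x m.
box_iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(), n, m))
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  u <- outer(box_area(a), box_area(b), `+`) - inter
  out <- inter / u
  out[u <= 0] <- 0
  out
}

clip_boxes <- function(boxes, height, width) {
  boxes <- as_box_matrix(boxes)
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), width)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), height)
  boxes
}

# Delta encoding between proposal boxes and targets (dx, dy, dw, dh),
# normalized by the usual detection standard deviations.
bbox_encode <- function(proposals, gt, stds = c(0.1, 0.1, 0.2, 0.2)) {
  p <- as_box_matrix(proposals); g <- as_box_matrix(gt)
  pw <- p[, 3] - p[, 1]; ph <- p[, 4] - p[, 2]
  px <- p[, 1] + pw / 2; py <- p[, 2] + ph / 2
  gw <- g[, 3] - g[, 1]; gh <- g[, 4] - g[, 2]
  gx <- g[, 1] + gw / 2; gy <- g[, 2] + gh / 2
  d <- cbind((gx - px) / pw, (gy - py) / ph, log(gw / pw), log(gh / ph))
  sweep(d, 2L, stds, `/`)
}

bbox_decode <- function(proposals, deltas, stds = c(0.1, 0.1, 0.2, 0.2),
                        max_ratio = 4) {
  p <- as_box_matrix(proposals)
  d <- sweep(as.matrix(deltas), 2L, stds, `*`)
  d[, 3] <- pmin(pmax(d[, 3], -max_ratio), max_ratio)
  d[, 4] <- pmin(pmax(d[, 4], -max_ratio), max_ratio)
  pw <- p[, 3] - p[, 1]; ph <- p[, 4] - p[, 2]
  px <- p[, 1] + pw / 2; py <- p[, 2] + ph / 2
  cx <- px + d[, 1] * pw; cy <- py + d[, 2] * ph
  w <- pw * exp(d[, 3]); h <- ph * exp(d[, 4])
  cbind(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
}
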
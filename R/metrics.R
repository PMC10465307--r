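# COCO-style evaluation: IoU, greedy matching, precision/recall, and
# 101-point interpolated average precision, with the size-stratified
# variants APs (area < 32^2) and APm (32^2 .. 96^2). AP over IoU 0.5:0.05:0.95
# and AP0.5 are reported for boxes and masks; APl is not reported (berries
# larger than 96^2 px are essentially absent from the emulated data).

#' Intersection over union of two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return popcount(and) / popcount(or); 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask_iou: shape mismatch")
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

mask_iou_matrix <- function(amasks, bmasks) {
  out <- matrix(0, length(amasks), length(bmasks))
  for (i in seq_along(amasks)) for (j in seq_along(bmasks))
    out[i, j] <- mask_iou(amasks[[i]], bmasks[[j]])
  out
}

#' Greedy score-ordered matching with precision/recall curve
#'
#' Detections are taken in descending score order; each is matched to the
#' unmatched ground truth of highest IoU at or above `iou_thresh` (ties at
#' the threshold count as matches). Precision = TP/(TP+FP) and
#' Recall = TP/(TP+FN) are accumulated along the ranked list.
#'
#' @param det_boxes n x 4 detection boxes (or list of masks with
#'   `iou_fn = mask_iou`).
#' @param scores detection confidences.
#' @param gt_boxes m x 4 ground-truth boxes (or list of masks).
#' @param iou_thresh matching threshold.
#' @param iou_fn either [iou()] or [mask_iou()]; picked automatically from
#'   the input type when `NULL`.
#' @return list with `tp`, `fp`, `fn`, per-detection `matched` flags (score
#'   order), and cumulative `precision` / `recall` vectors.
#' @export
match_and_pr <- function(det_boxes, scores, gt_boxes, iou_thresh = 0.5,
                         iou_fn = NULL) {
  is_mask <- is.list(det_boxes) && !is.data.frame(det_boxes)
  ious <- if (is_mask) mask_iou_matrix(det_boxes, gt_boxes)
          else box_iou_matrix(det_boxes, gt_boxes)
  if (!is.null(iou_fn)) {
    n <- if (is_mask) length(det_boxes) else nrow(as_box_matrix(det_boxes))
    m <- if (is_mask) length(gt_boxes) else nrow(as_box_matrix(gt_boxes))
    ious <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m))
      ious[i, j] <- if (is_mask) iou_fn(det_boxes[[i]], gt_boxes[[j]])
                    else iou_fn(as_box_matrix(det_boxes)[i, ],
                                as_box_matrix(gt_boxes)[j, ])
  }
  nd <- nrow(ious); ng <- ncol(ious)
  ord <- order(-scores)
  gt_taken <- rep(FALSE, ng)
  matched <- rep(FALSE, nd)
  for (k in seq_len(nd)) {
    d <- ord[k]
    if (ng == 0L) break
    cand <- which(!gt_taken & ious[d, ] >= iou_thresh)
    if (!length(cand)) next
    g <- cand[which.max(ious[d, cand])]
    gt_taken[g] <- TRUE
    matched[d] <- TRUE
  }
  msorted <- matched[ord]
  tp_cum <- cumsum(msorted)
  fp_cum <- cumsum(!msorted)
  list(tp = sum(matched), fp = nd - sum(matched), fn = ng - sum(matched),
       matched = msorted,
       precision = if (nd) tp_cum / (tp_cum + fp_cum) else numeric(),
       recall = if (nd) tp_cum / max(ng, 1L) else numeric())
}

#' 101-point interpolated average precision
#'
#' COCO convention: the precision curve is replaced by its running maximum
#' from the right (precision envelope) and sampled at 101 equally spaced
#' recall levels 0, 0.01, ..., 1.
#'
#' @param pr list with cumulative `precision` and `recall` (e.g. from
#'   [match_and_pr()]).
#' @param n_gt number of ground truths; `NA` AP when 0 (undefined category).
#' @return AP in \[0, 1\], or `NA` when undefined.
#' @export
average_precision <- function(pr, n_gt = NULL) {
  if (!is.null(n_gt) && n_gt == 0) return(NA_real_)
  p <- pr$precision; r <- pr$recall
  if (!length(p)) return(0)
  p <- rev(cummax(rev(p)))
  rec_thrs <- seq(0, 1, by = 0.01)
  idx <- findInterval(rec_thrs, r, left.open = TRUE) + 1L  # first r >= thr
  q <- ifelse(idx <= length(p), p[idx], 0)
  mean(q)
}

# Per-image COCO matching at a set of IoU thresholds within one area range.
# Follows the reference evaluator: ground truths outside the range are
# "ignore"; detections may match them (and are then ignored themselves);
# unmatched detections whose own area is outside the range are ignored.
coco_eval_image <- function(ious, det_scores, det_areas, gt_areas,
                            iou_thrs, area_rng, max_dets) {
  ng <- length(gt_areas)
  gt_ig <- gt_areas < area_rng[1] | gt_areas > area_rng[2]
  gt_ord <- order(gt_ig)                      # ignored ground truths last
  dt_ord <- order(-det_scores)
  if (length(dt_ord) > max_dets) dt_ord <- dt_ord[seq_len(max_dets)]
  nd <- length(dt_ord)
  nt <- length(iou_thrs)
  dtm <- matrix(0L, nt, nd)
  dt_ignore <- matrix(FALSE, nt, nd)
  for (ti in seq_len(nt)) {
    t <- iou_thrs[ti]
    taken <- rep(FALSE, ng)
    for (di in seq_len(nd)) {
      d <- dt_ord[di]
      best <- min(t, 1 - 1e-10)
      m <- 0L
      for (gi in seq_len(ng)) {
        g <- gt_ord[gi]
        if (taken[g]) next
        if (m > 0L && !gt_ig[m] && gt_ig[g]) break
        if (ious[d, g] < best) next
        best <- ious[d, g]
        m <- g
      }
      if (m > 0L) {
        taken[m] <- TRUE
        dtm[ti, di] <- m
        dt_ignore[ti, di] <- gt_ig[m]
      }
    }
    out_rng <- det_areas[dt_ord] < area_rng[1] |
               det_areas[dt_ord] > area_rng[2]
    dt_ignore[ti, ] <- dt_ignore[ti, ] | (dtm[ti, ] == 0L & out_rng)
  }
  list(scores = det_scores[dt_ord], dtm = dtm, dt_ignore = dt_ignore,
       n_pos = sum(!gt_ig))
}

# Accumulate AP over images for one IoU-threshold vector and area range.
coco_accumulate <- function(per_image, iou_thrs) {
  npig <- sum(vapply(per_image, `[[`, numeric(1), "n_pos"))
  if (npig == 0) return(rep(NA_real_, length(iou_thrs)))
  all_scores <- unlist(lapply(per_image, `[[`, "scores"))
  ord <- order(-all_scores)
  vapply(seq_along(iou_thrs), function(ti) {
    tps <- unlist(lapply(per_image, function(e)
      e$dtm[ti, ] > 0L & !e$dt_ignore[ti, ]))
    igs <- unlist(lapply(per_image, function(e) e$dt_ignore[ti, ]))
    tps <- tps[ord]; igs <- igs[ord]
    tps <- tps[!igs]
    if (!length(tps)) return(0)
    tp_cum <- cumsum(tps)
    fp_cum <- cumsum(!tps)
    average_precision(list(precision = tp_cum / (tp_cum + fp_cum),
                           recall = tp_cum / npig))
  }, numeric(1))
}

#' COCO-style AP report for boxes and masks
#'
#' Computes AP0.5, AP (mean over IoU 0.50:0.05:0.95), APs (area < 32^2) and
#' APm (32^2 .. 96^2) for box IoU and mask IoU separately. Size strata use
#' ground-truth annotation areas (visible mask pixels).
#'
#' @param dets per-image list: each element a list with `boxes` (n x 4
#'   corner matrix), `scores`, and optionally `masks` (list of logical
#'   matrices).
#' @param gts per-image list: `boxes`, `areas`, and optionally `masks`.
#' @param max_dets detections kept per image (COCO default 100; raise for
#'   counting workloads with >100 berries per bunch).
#' @param types any of "box", "mask" (mask entries required for "mask").
#' @return list of class `ap_report`: `$box` and `$mask`, each with `ap50`,
#'   `ap`, `ap_s`, `ap_m` in \[0, 1\] (`NA` for empty strata).
#' @export
coco_ap_suite <- function(dets, gts, max_dets = 100L,
                          types = c("box", "mask")) {
  if (length(dets) != length(gts))
    stop("coco_ap_suite: dets and gts must have one entry per image")
  if (!length(gts) || !sum(vapply(gts, function(g) length(g$areas),
                                  numeric(1))))
    stop("coco_ap_suite: no ground-truth annotations")
  iou_thrs <- seq(0.5, 0.95, by = 0.05)
  ranges <- list(all = c(0, 1e10), small = c(0, 32^2),
                 medium = c(32^2, 96^2))
  out <- list()
  for (type in types) {
    per_rng <- lapply(ranges, function(rng) {
      per_image <- lapply(seq_along(gts), function(i) {
        g <- gts[[i]]; d <- dets[[i]]
        nd <- if (is.null(d$scores)) 0L else length(d$scores)
        if (type == "mask") {
          ious <- mask_iou_matrix(d$masks %||% list(), g$masks %||% list())
          det_areas <- vapply(d$masks %||% list(), sum, numeric(1))
        } else {
          ious <- box_iou_matrix(d$boxes %||% matrix(numeric(), 0, 4),
                                 g$boxes)
          det_areas <- box_area(d$boxes %||% matrix(numeric(), 0, 4))
        }
        coco_eval_image(ious, d$scores %||% numeric(), det_areas, g$areas,
                        iou_thrs, rng, max_dets)
      })
      coco_accumulate(per_image, iou_thrs)
    })
    ap_all <- per_rng$all
    out[[type]] <- list(ap50 = ap_all[1],
                        ap = mean(ap_all),
                        ap_s = mean(per_rng$small),
                        ap_m = mean(per_rng$medium))
  }
  structure(out, class = "ap_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ap_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "  --", sprintf("%5.1f", 100 * v))
  for (type in names(x)) {
    r <- x[[type]]
    cat(sprintf("%-5s AP0.5 %s  AP %s  APs %s  APm %s\n", type,
                fmt(r$ap50), fmt(r$ap), fmt(r$ap_s), fmt(r$ap_m)))
  }
  invisible(x)
}
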
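# Independent oracle implementations used to validate the package's
# vectorized code paths. These are deliberately naive, loop-based
# transcriptions of the defining formulas, kept separate from the package
# internals.

# Literal Gaussian Soft-NMS: repeatedly pop the argmax-score box into the
# kept set and decay every remaining score by exp(-IoU^2 / sigma).
oracle_soft_nms <- function(boxes, scores, sigma, score_thresh) {
  pair_iou <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    areas <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2])
    if (areas - inter <= 0) 0 else inter / (areas - inter)
  }
  remaining <- seq_along(scores)
  s <- scores
  kept <- integer(0)
  kept_s <- numeric(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (i in remaining) if (s[i] > s[best]) best <- i
    kept <- c(kept, best)
    kept_s <- c(kept_s, s[best])
    remaining <- remaining[remaining != best]
    drop <- c()
    for (i in remaining) {
      ov <- pair_iou(boxes[best, ], boxes[i, ])
      s[i] <- s[i] * exp(-ov^2 / sigma)
      if (s[i] < score_thresh) drop <- c(drop, i)
    }
    remaining <- setdiff(remaining, drop)
  }
  list(kept = kept, scores = kept_s)
}

# Literal transcription of the reference COCO evaluator (evaluateImg +
# accumulate): per-image greedy matching over sorted detections with ignore
# handling, then 101-point interpolated precision averaged over recall
# thresholds.
oracle_coco_eval <- function(dets, gts, iou_mode = "box", max_dets = 100,
                             area_rng = c(0, 1e10)) {
  iou_thrs <- seq(0.5, 0.95, by = 0.05)
  rec_thrs <- seq(0, 1, by = 0.01)
  n_img <- length(gts)

  eval_imgs <- vector("list", n_img)
  for (im in seq_len(n_img)) {
    g <- gts[[im]]
    d <- dets[[im]]
    ng <- length(g$areas)
    nd <- length(d$scores)
    if (iou_mode == "box") {
      gboxes <- g$boxes
      dboxes <- d$boxes
      ious <- matrix(0, nd, ng)
      if (nd && ng) for (i in 1:nd) for (j in 1:ng) {
        a <- dboxes[i, ]; b <- gboxes[j, ]
        ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
        iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
        inter <- ix * iy
        un <- (a[3] - a[1]) * (a[4] - a[2]) +
          (b[3] - b[1]) * (b[4] - b[2]) - inter
        ious[i, j] <- if (un > 0) inter / un else 0
      }
      dareas <- if (nd) (dboxes[, 3] - dboxes[, 1]) *
        (dboxes[, 4] - dboxes[, 2]) else numeric()
    } else {
      ious <- matrix(0, nd, ng)
      if (nd && ng) for (i in 1:nd) for (j in 1:ng) {
        inter <- sum(d$masks[[i]] & g$masks[[j]])
        un <- sum(d$masks[[i]] | g$masks[[j]])
        ious[i, j] <- if (un > 0) inter / un else 0
      }
      dareas <- vapply(d$masks, sum, numeric(1))
    }
    gt_ig <- g$areas < area_rng[1] | g$areas > area_rng[2]
    gord <- order(gt_ig)
    dord <- order(-d$scores)
    if (length(dord) > max_dets) dord <- dord[1:max_dets]
    ndk <- length(dord)
    dtm <- matrix(0, length(iou_thrs), ndk)
    dtIg <- matrix(FALSE, length(iou_thrs), ndk)
    for (ti in seq_along(iou_thrs)) {
      gtm <- rep(0, ng)
      for (di in seq_len(ndk)) {
        dd <- dord[di]
        iou_best <- min(iou_thrs[ti], 1 - 1e-10)
        m <- -1
        for (gi in seq_len(ng)) {
          gg <- gord[gi]
          if (gtm[gg] > 0) next
          if (m > -1 && !gt_ig[m] && gt_ig[gg]) break
          if (ious[dd, gg] < iou_best) next
          iou_best <- ious[dd, gg]
          m <- gg
        }
        if (m > -1) {
          gtm[m] <- dd
          dtm[ti, di] <- m
          dtIg[ti, di] <- gt_ig[m]
        }
      }
      for (di in seq_len(ndk)) {
        if (dtm[ti, di] == 0 &&
            (dareas[dord[di]] < area_rng[1] ||
             dareas[dord[di]] > area_rng[2]))
          dtIg[ti, di] <- TRUE
      }
    }
    eval_imgs[[im]] <- list(scores = d$scores[dord], dtm = dtm, dtIg = dtIg,
                            npos = sum(!gt_ig))
  }

  npig <- sum(vapply(eval_imgs, function(e) e$npos, numeric(1)))
  if (npig == 0) return(rep(NA_real_, length(iou_thrs)))
  all_scores <- unlist(lapply(eval_imgs, function(e) e$scores))
  ord <- order(-all_scores)
  ap <- numeric(length(iou_thrs))
  for (ti in seq_along(iou_thrs)) {
    tps <- unlist(lapply(eval_imgs, function(e)
      e$dtm[ti, ] > 0 & !e$dtIg[ti, ]))[ord]
    igs <- unlist(lapply(eval_imgs, function(e) e$dtIg[ti, ]))[ord]
    tps <- tps[!igs]
    if (!length(tps)) { ap[ti] <- 0; next }
    tp_cum <- cumsum(tps)
    fp_cum <- cumsum(!tps)
    pr <- tp_cum / (tp_cum + fp_cum)
    rc <- tp_cum / npig
    # precision envelope
    for (i in rev(seq_along(pr))[-1]) if (pr[i] < pr[i + 1]) pr[i] <- pr[i + 1]
    q <- numeric(length(rec_thrs))
    for (ri in seq_along(rec_thrs)) {
      hit <- which(rc >= rec_thrs[ri])
      q[ri] <- if (length(hit)) pr[hit[1]] else 0
    }
    ap[ti] <- mean(q)
  }
  ap
}

# Full oracle AP report mirroring coco_ap_suite's fields.
oracle_ap_report <- function(dets, gts, iou_mode = "box", max_dets = 100) {
  all <- oracle_coco_eval(dets, gts, iou_mode, max_dets, c(0, 1e10))
  small <- oracle_coco_eval(dets, gts, iou_mode, max_dets, c(0, 32^2))
  med <- oracle_coco_eval(dets, gts, iou_mode, max_dets, c(32^2, 96^2))
  list(ap50 = all[1], ap = mean(all), ap_s = mean(small), ap_m = mean(med))
}

# Random detection/ground-truth fixture on a small canvas, with masks.
random_eval_fixture <- function(seed, n_img = 2, canvas = 24L) {
  set.seed(seed)
  mk_mask <- function(box) {
    m <- matrix(FALSE, canvas, canvas)
    x0 <- max(1, round(box[1]) + 1); x1 <- min(canvas, round(box[3]))
    y0 <- max(1, round(box[2]) + 1); y1 <- min(canvas, round(box[4]))
    if (x1 >= x0 && y1 >= y0) m[y0:y1, x0:x1] <- TRUE
    # carve a random corner out so masks are not plain rectangles
    if (runif(1) < 0.5 && x1 > x0 && y1 > y0)
      m[y0:(y0 + (y1 - y0) %/% 2), x0:(x0 + (x1 - x0) %/% 2)] <- FALSE
    m
  }
  mk_set <- function(n) {
    w <- runif(n, 2, 14); h <- runif(n, 2, 14)
    x <- runif(n, 0, canvas - w); y <- runif(n, 0, canvas - h)
    boxes <- cbind(x1 = x, y1 = y, x2 = x + w, y2 = y + h)
    masks <- lapply(seq_len(n), function(i) mk_mask(boxes[i, ]))
    list(boxes = boxes, masks = masks)
  }
  gts <- lapply(seq_len(n_img), function(i) {
    ng <- sample(1:4, 1)
    s <- mk_set(ng)
    list(boxes = s$boxes, masks = s$masks,
         areas = vapply(s$masks, sum, numeric(1)))
  })
  dets <- lapply(seq_len(n_img), function(i) {
    nd <- sample(0:6, 1)
    if (nd == 0)
      return(list(boxes = matrix(numeric(), 0, 4), scores = numeric(),
                  masks = list()))
    # mix of perturbed ground-truth boxes and random boxes
    g <- gts[[i]]$boxes
    pick <- sample(nrow(g), nd, replace = TRUE)
    base <- g[pick, , drop = FALSE] + matrix(rnorm(nd * 4, 0, 2), nd, 4)
    base[, 3] <- pmax(base[, 3], base[, 1] + 1)
    base[, 4] <- pmax(base[, 4], base[, 2] + 1)
    boxes <- pmin(pmax(base, 0), canvas)
    boxes[, 3] <- pmax(boxes[, 3], boxes[, 1] + 0.5)
    boxes[, 4] <- pmax(boxes[, 4], boxes[, 2] + 0.5)
    list(boxes = boxes, scores = runif(nd),
         masks = lapply(seq_len(nd), function(k) mk_mask(boxes[k, ])))
  })
  list(dets = dets, gts = gts)
}

# Grid-perturbation check that (k, b) minimizes the squared loss locally.
oracle_grid_optimal <- function(pairs, k, b, span = 0.5, n = 101) {
  loss <- function(kk, bb) mean((kk * pairs$predicted + bb - pairs$actual)^2)
  l0 <- loss(k, b)
  for (kk in seq(k - span, k + span, length.out = n))
    for (bb in seq(b - span, b + span, length.out = n))
      if (loss(kk, bb) < l0 - 1e-12) return(FALSE)
  TRUE
}
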
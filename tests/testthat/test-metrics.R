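# COCO-style metrics: IoU geometry, greedy matching, interpolated AP, and
# equivalence with the literal reference-evaluator transcription.

test_that("box IoU follows the intersection-over-union geometry", {
  expect_equal(iou(c(0, 0, 4, 4), c(0, 0, 4, 4)), 1)
  expect_equal(iou(c(0, 0, 4, 4), c(10, 10, 12, 12)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(c(0, 0, 0, 5), c(0, 0, 2, 2)), 0)  # degenerate box
})

test_that("mask IoU counts pixels, with empty-union and shape guards", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  half <- matrix(FALSE, 4, 4); half[1:2, 1] <- TRUE  # 2 px subset of 4 px
  expect_equal(mask_iou(a, half), 0.5)
  expect_equal(mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  expect_error(mask_iou(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("greedy matching accumulates precision and recall", {
  gt <- matrix(c(0, 0, 10, 10), 1, 4, byrow = TRUE)
  m <- match_and_pr(matrix(c(0, 0, 10, 10), 1), 0.9, gt, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  # duplicate perfect detections: the single-match rule makes one an FP
  dup <- match_and_pr(matrix(c(0, 0, 10, 10, 0, 0, 10, 10), 2, byrow = TRUE),
                      c(0.9, 0.8), gt, 0.5)
  expect_equal(c(dup$tp, dup$fp), c(1, 1))
  # 3 gts, 4 dets of which 2 match: P = 0.5, R = 2/3
  gt3 <- matrix(c(0, 0, 10, 10, 20, 0, 30, 10, 40, 0, 50, 10), 3,
                byrow = TRUE)
  det4 <- matrix(c(0, 0, 10, 10, 20, 0, 30, 10,
                   70, 0, 80, 10, 70, 20, 80, 30), 4, byrow = TRUE)
  mm <- match_and_pr(det4, c(0.9, 0.8, 0.7, 0.6), gt3, 0.5)
  expect_equal(c(mm$tp, mm$fp, mm$fn), c(2, 2, 1))
  expect_equal(mm$precision[length(mm$precision)], 0.5)
  expect_equal(mm$recall[length(mm$recall)], 2 / 3)
  # invariants tp + fn = #gt, tp + fp = #det
  expect_equal(mm$tp + mm$fn, 3)
  expect_equal(mm$tp + mm$fp, 4)
})

test_that("interpolated AP hits its boundary values", {
  gt <- matrix(c(0, 0, 10, 10, 20, 0, 30, 10), 2, byrow = TRUE)
  perfect <- match_and_pr(gt, c(0.9, 0.8), gt, 0.5)
  expect_equal(average_precision(perfect), 1)
  misses <- match_and_pr(matrix(c(50, 50, 60, 60), 1), 0.9, gt, 0.5)
  expect_equal(average_precision(misses), 0)
  expect_true(is.na(average_precision(perfect, n_gt = 0)))
})

test_that("the AP suite is exact on perfect detections", {
  sc <- generate_bunch_scene(scene_spec(image_height = 96, image_width = 96,
                                        berry_count = 6,
                                        radius_range = c(5, 12), seed = 21))
  gt <- scene_ground_truth(sc)
  dets <- list(list(boxes = gt$boxes, scores = rep(1, nrow(gt$boxes)),
                    masks = gt$masks))
  rep <- coco_ap_suite(dets, list(gt))
  expect_equal(rep$box$ap50, 1)
  expect_equal(rep$box$ap, 1)
  expect_equal(rep$mask$ap50, 1)
  expect_equal(rep$mask$ap, 1)
  expect_error(coco_ap_suite(dets, list(list(boxes = matrix(numeric(), 0, 4),
                                             areas = numeric(),
                                             masks = list()))),
               "no ground-truth")
})

test_that("the AP suite matches the reference-evaluator transcription", {
  worst <- 0
  for (s in 1:100) {
    fx <- random_eval_fixture(s)
    rep <- coco_ap_suite(fx$dets, fx$gts, max_dets = 100)
    for (mode in c("box", "mask")) {
      oracle <- oracle_ap_report(fx$dets, fx$gts, mode)
      got <- rep[[mode]]
      for (f in c("ap50", "ap", "ap_s", "ap_m")) {
        expect_equal(is.na(got[[f]]), is.na(oracle[[f]]),
                     info = sprintf("seed %d %s %s NA-ness", s, mode, f))
        if (!is.na(got[[f]]))
          worst <- max(worst, abs(got[[f]] - oracle[[f]]))
      }
      expect_lte(got$ap, got$ap50 + 1e-12)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("removing an isolated true positive never improves any AP field", {
  # a fresh ground truth is planted in free space with one exact-duplicate,
  # top-scored detection: a true positive at every IoU threshold (and
  # ignored alongside its ground truth in out-of-range strata) that no other
  # detection can claim once deleted. Deleting it can then only lose recall.
  # (Deleting a TP that *shares* its ground truth with other overlapping
  # detections can legitimately raise AP by promoting a duplicate from FP
  # to TP, so isolation is part of the property.)
  plant_free_box <- function(fx, img, side = 4) {
    occupied <- rbind(fx$gts[[img]]$boxes, fx$dets[[img]]$boxes)
    for (x0 in seq(0, 24 - side)) for (y0 in seq(0, 24 - side)) {
      cand <- c(x0, y0, x0 + side, y0 + side)
      ious <- vapply(seq_len(nrow(occupied)), function(i)
        iou(cand, occupied[i, ]), numeric(1))
      if (all(ious == 0)) return(cand)
    }
    NULL
  }
  tested <- 0
  for (s in c(3, 17, 42, 55)) {
    fx <- random_eval_fixture(s)
    box <- plant_free_box(fx, 1)
    if (is.null(box)) next
    tested <- tested + 1
    mask <- matrix(FALSE, 24, 24)
    mask[(box[2] + 1):box[4], (box[1] + 1):box[3]] <- TRUE
    g <- fx$gts[[1]]
    fx$gts[[1]] <- list(boxes = rbind(g$boxes, box),
                        areas = c(g$areas, sum(mask)),
                        masks = c(g$masks, list(mask)))
    d <- fx$dets[[1]]
    fx_with <- fx
    fx_with$dets[[1]] <- list(boxes = rbind(matrix(box, 1), d$boxes),
                              scores = c(2, d$scores),
                              masks = c(list(mask), d$masks))
    base <- coco_ap_suite(fx_with$dets, fx_with$gts)
    dropped <- coco_ap_suite(fx$dets, fx$gts)
    for (mode in c("box", "mask")) for (f in c("ap50", "ap", "ap_s", "ap_m")) {
      a <- base[[mode]][[f]]; b <- dropped[[mode]][[f]]
      if (!is.na(a) && !is.na(b)) expect_lte(b, a + 1e-9)
    }
  }
  expect_gte(tested, 2)
})
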
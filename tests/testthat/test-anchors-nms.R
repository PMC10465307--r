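# Anchor generation (berry-optimized and default scales), dataset box
# statistics, and candidate suppression (Gaussian Soft-NMS vs its
# brute-force oracle, hard NMS baseline).

test_that("anchor sides follow (stride * scale) with area-preserving ratios", {
  shapes <- list(c(2, 2), c(2, 2), c(1, 1), c(1, 1), c(1, 1))
  opt <- generate_anchors(anchor_config(scale = 2), shapes)
  # square anchors (ratio 1 is the second of ratios 0.5, 1, 2)
  sides <- vapply(opt, function(a) unname(a[2, 3] - a[2, 1]), numeric(1))
  expect_equal(sides, c(8, 16, 32, 64, 128))
  def <- generate_anchors(anchor_config(scale = 8), shapes)
  sides8 <- vapply(def, function(a) unname(a[2, 3] - a[2, 1]), numeric(1))
  expect_equal(sides8, c(32, 64, 128, 256, 512))
  # ratio 0.5 at stride 4, scale 2: area 64, w = sqrt(32), h = sqrt(128)
  r05 <- opt[[1]][1, ]
  expect_equal(unname(r05[3] - r05[1]), sqrt(64 * 0.5), tolerance = 1e-10)
  expect_equal(unname(r05[4] - r05[2]), sqrt(64 / 0.5), tolerance = 1e-10)
})

test_that("anchors preserve area at every level and ratio, tiled on centres", {
  cfg <- anchor_config(scale = 2)
  shapes <- list(c(3, 4), c(3, 4), c(2, 2), c(2, 2), c(1, 1))
  anch <- generate_anchors(cfg, shapes)
  for (l in seq_along(anch)) {
    a <- anch[[l]]
    expect_equal(nrow(a), prod(shapes[[l]]) * 3)
    w <- a[, 3] - a[, 1]; h <- a[, 4] - a[, 2]
    expect_lt(max(abs(w * h - (cfg$strides[l] * cfg$scale)^2)), 1e-6)
    # first cell is centred at (0.5, 0.5) * stride
    ctr <- c((a[1, 1] + a[1, 3]) / 2, (a[1, 2] + a[1, 4]) / 2)
    expect_equal(unname(ctr), rep(0.5 * cfg$strides[l], 2))
  }
  expect_error(generate_anchors(cfg, list()), "empty")
  expect_error(anchor_config(strides = c(8, 4)), "increase")
  expect_error(anchor_config(scale = -1), "positive")
})

test_that("dataset box statistics summarize annotations and suggest scale 2", {
  mk_coco <- function(bboxes, hw = c(200, 200)) {
    list(images = list(list(id = 1, height = hw[1], width = hw[2])),
         annotations = lapply(seq_len(nrow(bboxes)), function(i)
           list(id = i, image_id = 1, bbox = bboxes[i, ],
                area = bboxes[i, 3] * bboxes[i, 4])))
  }
  one <- dataset_box_stats(mk_coco(matrix(c(0, 0, 10, 20), 1)))
  expect_equal(one$stats$aspect, 0.5)
  expect_equal(one$stats$area, 200)
  same <- dataset_box_stats(mk_coco(matrix(rep(c(5, 5, 12, 12), 4), 4,
                                           byrow = TRUE)))
  expect_true(all(vapply(same$histograms,
                         function(h) sum(h$counts > 0) == 1, logical(1))))
  expect_error(dataset_box_stats(list(images = list(),
                                      annotations = list())), "no annotations")
  # synthetic default dataset: areas inside the emulated band, scale 2 wins
  scenes <- lapply(1:4, function(i) generate_bunch_scene(scene_spec(seed = i)))
  dir <- withr::local_tempdir()
  write_coco_dataset(scenes, dir)
  st <- dataset_box_stats(read_coco_dataset(dir))
  expect_true(all(st$stats$area >= 60 & st$stats$area <= 10000))
  expect_equal(st$suggested_scale, 2)
  csv <- file.path(dir, "stats.csv")
  write_box_stats(st, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(st$stats))
})

test_that("Gaussian Soft-NMS decays overlapping scores as specified", {
  # disjoint boxes: decay factor exp(0) = 1, scores unchanged
  d <- data.frame(x1 = c(0, 20), y1 = c(0, 20), x2 = c(5, 25),
                  y2 = c(5, 25), score = c(0.7, 0.6))
  out <- soft_nms(d, sigma = 0.5, score_thresh = 0.05)
  expect_equal(out$score, c(0.7, 0.6))
  expect_equal(nrow(out), 2)
  # worked pair: IoU 0.5, second score 0.8 * exp(-0.25 / 0.5)
  d2 <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = c(10, 5),
                   score = c(0.9, 0.8))
  out2 <- soft_nms(d2, sigma = 0.5, score_thresh = 0.05)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$score[2], 0.8 * exp(-0.25 / 0.5), tolerance = 1e-12)
  expect_error(soft_nms(d2, sigma = 0), "sigma")
})

test_that("Soft-NMS equals the brute-force oracle on 1000 seeded fixtures", {
  worst <- 0
  for (s in 1:1000) {
    n <- (s %% 8L) + 1L
    fx <- random_box_fixture(n, seed = s)
    out <- soft_nms(fx, sigma = 0.5, score_thresh = 0.05)
    oracle <- oracle_soft_nms(as.matrix(fx[, 1:4]), fx$score, 0.5, 0.05)
    expect_identical(attr(out, "kept"), oracle$kept)
    worst <- max(worst, max(abs(out$score - oracle$scores)))
    # monotonicity: decayed scores never exceed the originals
    expect_true(all(out$score <= fx$score[attr(out, "kept")] + 1e-12))
  }
  expect_lt(worst, 1e-9)
})

test_that("hard NMS suppresses duplicates and keeps disjoint boxes", {
  dup <- data.frame(x1 = c(0, 0), y1 = c(0, 0), x2 = c(10, 10),
                    y2 = c(10, 10), score = c(0.9, 0.8))
  expect_equal(nrow(hard_nms(dup, iou_thresh = 0.5)), 1)
  far <- data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60),
                    y2 = c(10, 60), score = c(0.9, 0.8))
  expect_equal(nrow(hard_nms(far, iou_thresh = 0.5)), 2)
  expect_error(hard_nms(far, iou_thresh = 1.5), "iou_thresh")
  # sigma -> 0 Soft-NMS matches hard suppression on the overlapping pair
  d2 <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = c(10, 5),
                   score = c(0.9, 0.8))
  soft0 <- soft_nms(d2, sigma = 1e-9, score_thresh = 0.05)
  hard0 <- hard_nms(d2, iou_thresh = 0.4)
  expect_equal(attr(soft0, "kept"), attr(hard0, "kept"))
})

test_that("region proposals stay within bounds under either filtering mode", {
  cfg <- smoke_train_config(seed = 2)
  model <- build_model(cfg)
  sc <- generate_bunch_scene(easy_scene_spec(berry_count = 4, seed = 9))
  env <- asNamespace("berryseg")
  pyr <- env$model_pyramid(model, sc$image)
  hw <- dim(sc$image)[1:2]
  soft <- rpn_propose(pyr, model$heads$rpn, model$anchors, hw, mode = "soft",
                      pre_topk = 200, post_topk = 50)
  hard <- rpn_propose(pyr, model$heads$rpn, model$anchors, hw, mode = "hard",
                      pre_topk = 200, post_topk = 50)
  for (props in list(soft, hard)) {
    expect_lte(nrow(props), 50)
    expect_true(all(props$x1 >= 0 & props$y1 >= 0 &
                    props$x2 <= hw[2] & props$y2 <= hw[1]))
  }
  # filtering mode does not touch the head outputs: the argmax candidate
  # survives both modes with the same location
  expect_equal(unname(as.matrix(soft[1, 1:4])), unname(as.matrix(hard[1, 1:4])))
  expect_error(rpn_propose(pyr, model$heads$rpn, model$anchors, hw,
                           mode = "maybe"), "arg")
})
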
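# Synthetic bunch generator: determinism, occlusion bookkeeping, emulated
# size-distribution bands, and COCO round trips.

test_that("scene generation is bit-reproducible given the seed", {
  spec <- scene_spec(image_height = 96, image_width = 96, berry_count = 10,
                     radius_range = c(5, 16), seed = 42)
  a <- generate_bunch_scene(spec)
  b <- generate_bunch_scene(spec)
  expect_identical(a, b)
  expect_false(identical(
    a$image,
    generate_bunch_scene(scene_spec(image_height = 96, image_width = 96,
                                    berry_count = 10,
                                    radius_range = c(5, 16),
                                    seed = 43))$image))
})

test_that("zero overlap with full visibility yields disjoint berries, all counted", {
  spec <- scene_spec(image_height = 160, image_width = 160, berry_count = 8,
                     radius_range = c(6, 12), overlap_level = 0,
                     min_visible_fraction = 1, seed = 3)
  sc <- generate_bunch_scene(spec)
  expect_equal(sc$true_count, 8)
  expect_equal(nrow(sc$instances), 8)
  expect_true(all(sc$instances$visible_fraction == 1))
  masks <- lapply(seq_len(8), function(k) instance_mask(sc, k))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(sum(masks[[i]] & masks[[j]]), 0)
})

test_that("default-spec berries stay inside the emulated statistical bands", {
  stats <- NULL
  sd <- 0
  while (is.null(stats) || nrow(stats) < 1000) {
    sd <- sd + 1
    sc <- generate_bunch_scene(scene_spec(seed = sd))
    stats <- rbind(stats, sc$instances)
  }
  expect_true(all(stats$w >= 5 & stats$w <= 100))
  expect_true(all(stats$h >= 5 & stats$h <= 100))
  expect_true(all(stats$w / stats$h >= 0.5 & stats$w / stats$h <= 2))
  expect_true(all(stats$area >= 60 & stats$area <= 10000))
})

test_that("annotations are consistent: tight boxes and exact areas", {
  for (sd in 1:100) {
    sc <- generate_bunch_scene(scene_spec(image_height = 96, image_width = 96,
                                          berry_count = 8,
                                          radius_range = c(5, 18),
                                          seed = sd))
    expect_equal(sc$true_count, nrow(sc$instances))
    for (k in seq_len(nrow(sc$instances))) {
      msk <- instance_mask(sc, k)
      expect_gt(sum(msk), 0)
      rr <- range(which(rowSums(msk) > 0))
      cc <- range(which(colSums(msk) > 0))
      inst <- sc$instances[k, ]
      expect_equal(inst$x, cc[1] - 1)
      expect_equal(inst$y, rr[1] - 1)
      expect_equal(inst$w, cc[2] - cc[1] + 1)
      expect_equal(inst$h, rr[2] - rr[1] + 1)
      expect_equal(inst$area, sum(msk))
    }
  }
})

test_that("degenerate scene specifications are rejected", {
  expect_error(scene_spec(image_height = 0), "32x32")
  expect_error(scene_spec(berry_count = 0), "berry_count")
  expect_error(scene_spec(radius_range = c(1, 10)), "radius_range")
  expect_error(scene_spec(radius_range = c(20, 10)), "radius_range")
  expect_error(scene_spec(aspect_range = c(0.3, 1)), "aspect_range")
  expect_error(scene_spec(min_visible_fraction = 0), "min_visible_fraction")
  expect_error(scene_spec(image_height = 40, image_width = 40,
                          radius_range = c(20, 40)), "too small")
})

test_that("random box fixtures are valid, canvas-bounded and seeded", {
  expect_equal(nrow(random_box_fixture(0)), 0)
  a <- random_box_fixture(10, seed = 7)
  b <- random_box_fixture(10, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$x1 < a$x2 & a$y1 < a$y2))
  expect_true(all(a$x1 >= 0 & a$y1 >= 0 & a$x2 <= 100 & a$y2 <= 100))
  expect_true(all(a$score >= 0.05 & a$score <= 1))
})

test_that("RLE encoding round-trips masks exactly", {
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(runif(30 * 17) < 0.3, 30, 17)
    expect_identical(rle_decode(rle_encode(m)), m)
  }
  empty <- matrix(FALSE, 5, 5)
  expect_identical(rle_decode(rle_encode(empty)), empty)
  full <- matrix(TRUE, 4, 6)
  expect_identical(rle_decode(rle_encode(full)), full)
})

test_that("COCO datasets round-trip counts, areas and masks losslessly", {
  scenes <- list(
    generate_bunch_scene(scene_spec(image_height = 96, image_width = 96,
                                    berry_count = 3, radius_range = c(6, 12),
                                    overlap_level = 0,
                                    min_visible_fraction = 1, seed = 1)),
    generate_bunch_scene(scene_spec(image_height = 96, image_width = 96,
                                    berry_count = 5, radius_range = c(5, 12),
                                    seed = 2)))
  dir <- withr::local_tempdir()
  write_coco_dataset(scenes, dir)
  coco <- read_coco_dataset(dir)
  expect_length(coco$images, 2)
  n_ann <- vapply(scenes, function(s) nrow(s$instances), numeric(1))
  expect_length(coco$annotations, sum(n_ann))
  # first scene: 3 berries -> 3 annotation records for image 1
  expect_equal(sum(vapply(coco$annotations, function(a)
    a$image_id == 1, logical(1))), 3)
  # per-instance areas identical after the round trip
  for (im in 1:2) {
    gt <- coco_ground_truth(coco, im)
    expect_equal(gt$areas, scenes[[im]]$instances$area)
    sgt <- scene_ground_truth(scenes[[im]])
    expect_equal(unname(gt$boxes), unname(sgt$boxes))
    for (k in seq_along(gt$masks))
      expect_identical(gt$masks[[k]], sgt$masks[[k]])
  }
  # image pixels survive the PNG round trip
  img <- coco_load_image(coco, 1)
  expect_equal(dim(img), dim(scenes[[1]]$image))
  expect_lt(max(abs(img - round(scenes[[1]]$image))), 1.01)
  expect_error(write_coco_dataset(list(), withr::local_tempdir()), "empty")
})
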
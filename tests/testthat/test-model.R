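# Assembly toggles, configuration round trips, desk-scale training, and
# the evaluation pipeline with a perfect oracle injected.

test_that("configuration validates and round-trips through YAML", {
  cfg <- smoke_train_config(seed = 3, iterations = 7L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_train_config(cfg, path)
  back <- read_train_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(lr_decay_epochs = c(8, 13)), "decay epochs")
  expect_error(train_config(neck_channels = 8, compress = 16), "compress")
})

test_that("toggles assemble the ablation variants structurally", {
  base <- build_model(train_config(anchor_opt = FALSE, soft_nms = FALSE,
                                   asff = FALSE), materialize = FALSE)
  expect_s3_class(base$neck, "fpn_neck")
  expect_equal(base$anchors$scale, 8)
  expect_false(base$cfg$soft_nms)
  full <- build_model(train_config(), materialize = FALSE)
  expect_s3_class(full$neck, "asff_neck")
  expect_equal(full$anchors$scale, 2)
  # NMS is parameter-free: toggling it changes no trainable count
  soft_off <- build_model(train_config(soft_nms = FALSE),
                          materialize = FALSE)
  expect_equal(parameter_count(soft_off)$total,
               parameter_count(full)$total)
  grid <- ablation_grid(train_config())
  expect_equal(nrow(grid), 8)
  expect_equal(nrow(unique(grid[, c("anchor_opt", "soft_nms", "asff")])), 8)
  expect_equal(sort(unique(grid$anchor_scale)), c(2, 8))
})

test_that("seeded builds are identical; different seeds differ", {
  flatten_params <- asNamespace("berryseg")$flatten_params
  cfg <- smoke_train_config(seed = 11)
  a <- build_model(cfg)
  b <- build_model(cfg)
  expect_identical(flatten_params(a$heads), flatten_params(b$heads))
  expect_identical(a$backbone$patch_embed$conv$params$w,
                   b$backbone$patch_embed$conv$params$w)
  cfg2 <- smoke_train_config(seed = 12)
  c2 <- build_model(cfg2)
  expect_false(identical(a$backbone$patch_embed$conv$params$w,
                         c2$backbone$patch_embed$conv$params$w))
})

test_that("desk-scale training drives the loss down", {
  run <- smoke_run()
  h <- run$history
  expect_equal(nrow(h), 150)
  expect_true(all(is.finite(h$loss)))
  # the 50-iteration prefix is itself a completed seeded smoke run
  expect_lt(h$loss[50], h$loss[1])
  expect_lt(mean(tail(h$loss, 10)), mean(head(h$loss, 10)))
})

test_that("checkpoints round-trip and reproduce evaluation", {
  flatten_params <- asNamespace("berryseg")$flatten_params
  run <- smoke_run()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(run$model, path)
  restored <- load_checkpoint(path)
  sc <- smoke_scenes()[[1]]
  a <- detect_and_segment(run$model, sc$image, score_thresh = 0.3)
  b <- detect_and_segment(restored, sc$image, score_thresh = 0.3)
  expect_identical(a, b)
  # transfer initialization copies weights into a fresh assembly
  fresh <- build_model(smoke_train_config(seed = 99))
  moved <- init_from_checkpoint(fresh, path)
  expect_identical(flatten_params(moved$heads),
                   flatten_params(run$model$heads))
  expect_identical(moved$backbone$patch_embed$conv$params$w,
                   run$model$backbone$patch_embed$conv$params$w)
  bb_only <- init_from_checkpoint(fresh, path, backbone_only = TRUE)
  expect_identical(bb_only$backbone$patch_embed$conv$params$w,
                   run$model$backbone$patch_embed$conv$params$w)
  expect_false(identical(flatten_params(bb_only$heads),
                         flatten_params(run$model$heads)))
})

test_that("an injected perfect oracle drives the evaluation to its optimum", {
  scenes <- lapply(1:3, function(i)
    generate_bunch_scene(scene_spec(image_height = 128, image_width = 128,
                                    berry_count = 6 + 3 * i,
                                    radius_range = c(5, 14),
                                    seed = 70 + i)))
  out_dir <- withr::local_tempdir()
  ev <- evaluate_run(NULL, scenes, detector = oracle_detector(scenes),
                     out_dir = out_dir)
  expect_equal(ev$ap_report$box$ap, 1)
  expect_equal(ev$ap_report$box$ap50, 1)
  expect_equal(ev$ap_report$mask$ap, 1)
  expect_equal(ev$counts$predicted, ev$counts$actual)
  expect_equal(ev$fit$rmse, 0)
  expect_equal(ev$fit$r2, 1)
  expect_true(file.exists(file.path(out_dir, "ap_report.json")))
  expect_true(file.exists(file.path(out_dir, "counts.csv")))
  expect_true(file.exists(file.path(out_dir, "fit.json")))
})
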
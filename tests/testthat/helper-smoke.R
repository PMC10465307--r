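# Shared desk-scale training run, computed once per test session. Two easy
# synthetic scenes (large, well-separated, high-contrast berries), a reduced
# backbone/neck, and 150 head-training iterations on cached frozen features.

.smoke_env <- new.env(parent = emptyenv())

smoke_scenes <- function() {
  if (is.null(.smoke_env$scenes))
    .smoke_env$scenes <- lapply(1:2, function(i)
      generate_bunch_scene(easy_scene_spec(berry_count = 4L + i,
                                           seed = 50L + i)))
  .smoke_env$scenes
}

smoke_run <- function() {
  if (is.null(.smoke_env$run)) {
    cfg <- smoke_train_config(seed = 5L, iterations = 150L)
    .smoke_env$run <- train(cfg, smoke_scenes())
  }
  .smoke_env$run
}

smoke_detections <- function() {
  if (is.null(.smoke_env$dets)) {
    sc <- smoke_scenes()[[1]]
    .smoke_env$dets <- detect_and_segment(smoke_run()$model, sc$image,
                                          score_thresh = 0.3)
  }
  .smoke_env$dets
}
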
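# ASFF neck: resampling shape contracts for all 16 (source, target) pairs,
# softmax-normalized per-location fusion, saturation behaviour, gradient
# flow into the fusion logits, and the FPN ablation baseline.

micro_stages <- function(channels = c(4, 6, 8, 10), base = 32, seed = 11) {
  set.seed(seed)
  lapply(1:4, function(l) {
    hw <- base / 2^(l - 1)
    array(rnorm(hw * hw * channels[l]), c(hw, hw, channels[l]))
  })
}

test_that("resampling reaches every target level at the exact shape", {
  ch <- c(4, 6, 8, 10)
  nk <- asff_neck(ch, out_channels = 8, compress = 4, seed = 2)
  stages <- micro_stages(ch)
  for (src in 1:4) for (dst in 1:4) {
    dst_shape <- dim(stages[[dst]])[1:2]
    out <- resample_to_level(nk, stages[[src]], src, dst,
                             dst_shape = dst_shape)
    expect_equal(dim(out), c(dst_shape, 8),
                 info = sprintf("src %d -> dst %d", src, dst))
  }
  expect_error(resample_to_level(nk, stages[[1]], 0, 2), "levels")
  expect_error(resample_to_level(nk, stages[[1]], 1, 5), "levels")
})

test_that("fusion weights are a per-location softmax summing to one", {
  ch <- c(4, 6, 8, 10)
  nk <- asff_neck(ch, out_channels = 8, compress = 4, seed = 3)
  worst <- 0
  for (i in 1:100) {
    stages <- micro_stages(ch, base = 16, seed = 100 + i)
    fused <- asff_forward(nk, stages)
    for (wl in attr(fused, "fusion_weights")) {
      expect_true(all(wl > 0 & wl < 1))
      worst <- max(worst, max(abs(apply(wl, c(1, 2), sum) - 1)))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("fusion obeys the weighted-sum law and its limits", {
  set.seed(13)
  resized <- lapply(1:4, function(i) array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  # equal logits -> every weight 1/4
  w_eq <- array(0.25, c(4, 4, 4))
  y <- fuse_level(resized, w_eq)
  manual <- Reduce(`+`, resized) / 4
  expect_equal(y, manual, tolerance = 1e-12)
  # random softmax weights reproduce the explicit per-location sum
  logits <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  ex <- exp(logits)
  w <- ex / array(rep(apply(ex, c(1, 2), sum), 4), dim(ex))
  y2 <- fuse_level(resized, w)
  manual2 <- array(0, c(4, 4, 3))
  for (i in 1:4) for (j in 1:4) for (n in 1:4)
    manual2[i, j, ] <- manual2[i, j, ] + w[i, j, n] * resized[[n]][i, j, ]
  expect_equal(y2, manual2, tolerance = 1e-12)
  # saturated logits (t, 0, 0, 0) with t = 20 select the first map
  sat <- exp(c(20, 0, 0, 0)); sat <- sat / sum(sat)
  w_sat <- array(rep(sat, each = 16), c(4, 4, 4))
  expect_equal(fuse_level(resized, w_sat), resized[[1]], tolerance = 1e-4)
  # weights that do not sum to one are rejected
  expect_error(fuse_level(resized, w_eq * 1.1), "sum to 1")
  bad <- resized; bad[[2]] <- array(0, c(3, 3, 3))
  expect_error(fuse_level(bad, w_eq), "share one shape")
})

test_that("every fusion logit parameter receives gradient from the output", {
  nk <- asff_neck(c(2, 2, 2, 2), out_channels = 4, compress = 2, seed = 6)
  stages <- micro_stages(c(2, 2, 2, 2), base = 8, seed = 77)
  loss <- function(nkx)
    sum(unlist(lapply(asff_forward(nkx, stages, extra_level = FALSE), sum)))
  h <- 1e-4
  for (l in 1:4) for (pn in c("w", "b")) {
    p <- nk$levels[[l]]$weight_logits$params[[pn]]
    grads <- vapply(seq_along(p), function(i) {
      up <- nk; up$levels[[l]]$weight_logits$params[[pn]][i] <- p[i] + h
      dn <- nk; dn$levels[[l]]$weight_logits$params[[pn]][i] <- p[i] - h
      (loss(up) - loss(dn)) / (2 * h)
    }, numeric(1))
    expect_true(all(abs(grads) > 1e-10),
                info = sprintf("level %d %s", l, pn))
  }
})

test_that("the fused pyramid has the contracted strides and channels", {
  ch <- c(4, 6, 8, 10)
  nk <- asff_neck(ch, out_channels = 8, compress = 4, seed = 5)
  stages <- micro_stages(ch, base = 32)
  fused <- asff_forward(nk, stages)
  expect_named(fused, c("y1", "y2", "y3", "y4", "p_extra"))
  sizes <- vapply(fused, function(p) dim(p)[1], numeric(1))
  expect_equal(unname(sizes), c(32, 16, 8, 4, 2))
  expect_true(all(vapply(fused, function(p) dim(p)[3], numeric(1)) == 8))
})

test_that("the FPN baseline fuses top-down at matching shapes", {
  ch <- c(4, 6, 8, 10)
  fp <- fpn_neck(ch, out_channels = 8, seed = 5)
  stages <- micro_stages(ch, base = 32)
  fused <- fpn_forward(fp, stages)
  sizes <- vapply(fused, function(p) dim(p)[1], numeric(1))
  expect_equal(unname(sizes), c(32, 16, 8, 4, 2))
  expect_true(all(vapply(fused, function(p) dim(p)[3], numeric(1)) == 8))
})
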
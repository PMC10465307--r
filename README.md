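# berryseg

Instance segmentation and per-bunch counting of table-grape berries before
thinning, implemented natively in R.

Growers thin each grape cluster to a target berry number within a short
window early in the season; automating that requires counting the berries
of a single bunch from an RGB image. The berries are small (5–100 px at
network scale), leaf-coloured, and densely occluding — the hard corner of
instance segmentation. `berryseg` implements a two-stage detector
specialized for this regime:

* **Swin-Transformer-Tiny backbone** — hierarchical windowed attention
  producing a 4-level pyramid (strides 4/8/16/32, widths 96/192/384/768);
* **ASFF neck** — every level is resampled to every resolution and fused
  per location with softmax weights
  `Y^l_ij = α X^{1→l}_ij + β X^{2→l}_ij + γ X^{3→l}_ij + δ X^{4→l}_ij`,
  preserving fine detail for small berries;
* **berry-optimized anchors** — one scale per level multiplying the
  stride; scale 2 (sides 8–128 px) instead of the COCO default 8
  (32–512 px), derived from the dataset's box statistics;
* **Gaussian Soft-NMS** — `S_i ← S_i · exp(−IoU(M, b_i)²/σ)` keeps
  occluded neighbours that hard suppression would delete;
* **Mask R-CNN-style heads** — ROI-aligned box refinement and a fully
  convolutional 28×28 mask head;
* **COCO-style evaluation** — AP, AP0.5, APs, APm for boxes and masks;
* **count calibration** — least-squares `actual = k·predicted + b` with
  RMSE and R².

All layers (im2col convolutions, windowed attention, ROI align,
backpropagation for the detection heads) are implemented in base R matrix
algebra — no deep-learning framework required. A built-in synthetic
generator renders occluding elliptical berries with exact COCO annotations
so the entire pipeline is testable without any download. The full assembly
carries 50.71 M trainable parameters; the FPN/default-anchor baseline,
47.37 M.

## Worked example

```r
library(berryseg)

# two easy synthetic bunches (large, well-separated berries)
scenes <- lapply(1:2, function(i)
  generate_bunch_scene(easy_scene_spec(berry_count = 4 + i, seed = 50 + i)))

# desk-scale training: frozen backbone/neck, AdamW on the detection heads
cfg <- smoke_train_config(seed = 5, iterations = 150)
run <- train(cfg, scenes)
round(range(run$history$loss), 2)
#> [1] 0.28 2.91        # loss falls from ~2.9 to ~0.3

dets <- detect_and_segment(run$model, scenes[[1]]$image, score_thresh = 0.3)
count_berries(dets, score_thresh = 0.3)$predicted_count
#> [1] 5               # the scene contains 5 berries

m <- match_and_pr(dets$boxes, dets$scores, scene_ground_truth(scenes[[1]])$boxes, 0.5)
c(tp = m$tp, fp = m$fp, fn = m$fn)
#> tp fp fn
#>  5  2  0             # every berry recovered at IoU >= 0.5

# evaluation pipeline with a perfect oracle: must saturate
ev <- evaluate_run(NULL, scenes, detector = oracle_detector(scenes))
ev$ap_report
#> box   AP0.5 100.0  AP 100.0  APs 100.0  APm    --
#> mask  AP0.5 100.0  AP 100.0  APs 100.0  APm    --

# count calibration on (predicted, actual) pairs
fit <- fit_count_regression(data.frame(predicted = c(1, 2, 3),
                                       actual = c(2, 2, 5)))
glance(fit)
#>     k b     rmse   r2 n
#> 1 1.5 0 1.290994 0.75 3
```

The numbers above are what the code prints for these seeds; APm is `--`
because the easy scenes' berries all fall in the small-object stratum
(under 32² px of visible area).

A command-line interface wraps the same functions:

```sh
exec/berryseg synth --out ds --n-images 4 --berries 40,80 --seed 1
exec/berryseg stats --data ds --out stats.csv      # suggests anchor scale 2
exec/berryseg train --data ds --out ckpt.rds
exec/berryseg infer --weights ckpt.rds --image ds/images/img_00001.png --out dets
exec/berryseg eval --gt ds --dets dets.json
exec/berryseg count-fit --pairs pairs.csv --out fit.json
exec/berryseg ablate --out ablation.csv            # the 8 toggle combinations
```

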
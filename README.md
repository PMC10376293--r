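# capriDetect

Detection of small goat faces in livestock imagery. Faces captured by
pasture and barn cameras are routinely tiny — 8 to 55 px on a 1920×1080
frame, most side lengths between 24 and 32 px — blurred, clustered, and
easily swamped by background texture. `capriDetect` implements a
complete anchor-based one-stage detection toolkit built around three
ideas for that regime, together with the data pipeline, evaluation
metrics and model-comparison statistics needed to study it:

- **Context aggregation.** Each pyramid level is enriched by a context
  module: four parallel 3×3 dilated convolutions (rates 1–4) extract
  multi-scale local context, while the adjacent coarser/finer levels are
  resampled, gated by efficient channel attention (ECA), projected, and
  summed with it. At the pyramid ends the absent neighbor branch is
  simply dropped.
- **Feature-complementary fusion.** Pairs of pyramid levels are fused by
  cross-resolution elementwise products
  (`f12 = Conv(down(f1))·Conv(f2)`, `f21 = Conv(up(f2))·Conv(f1)`,
  then `Conv(f21)·Conv(up(f12))` and `Conv(f12)·Conv(down(f21))`), and
  the absolute difference of the up-path and down-path outputs
  suppresses background structure the two resolutions share; the
  difference maps are concatenated and reduced toward the finest or
  coarsest stride.
- **A width–height decomposed CIoU regression loss.** CIoU's single
  aspect-ratio penalty vanishes whenever the predicted and true aspect
  ratios agree, even when the absolute sizes are wrong. `wh-CIoU`
  penalizes the width and height ratios separately:

  ```
  wh-CIoU = IoU − ρ²(p_pr, p_gt)/d² − βε
  ε = (2/π²)[(arctan(w_pr/w_gt) − π/4)² + (arctan(h_pr/h_gt) − π/4)²]
  β = ε / ((1 − IoU) + ε)
  ```

  with `ρ` the center distance and `d` the diagonal of the smallest
  enclosing box. The localization loss is `1 − wh-CIoU`, combined as
  `Loss = 0.1·L_conf + 0.125·L_cls + 0.05·L_loc`.

Around that core the package provides Pascal VOC 2007 XML I/O, the
≤ 50 px small-target image filter, mosaic and mixup augmentation, a
fully seeded synthetic goat-scene generator (the field dataset is not
public), anchor clustering under the 1−IoU metric with the small-target
priors (5,9) … (72,146), greedy IoU-0.7 matching with precision /
recall / F1 / all-point AP, and Friedman + Nemenyi rank statistics for
comparing detectors across metrics. A compact CPU training engine
(reverse-mode autodiff over im2col convolutions, batch norm, SiLU,
bilinear resampling and attention gating, written in R with Rcpp
kernels) trains the full network at desk scale.

## Worked example

```r
library(capriDetect)

# geometry: the wh-CIoU of a prediction twice as wide as its target
gt <- boxCS(20, 20, 10, 8)
pr <- boxCS(20, 20, 20, 8)
boxWHCIoU(pr, gt)
#> [1] 0.4991553
localizationLoss(pr, gt, lossConfig(iouVariant = "wh_ciou"))
#> [1] 0.5008447

# model comparison on the published six-model benchmark ranks
rt <- RankTable(`rownames<-`(as.matrix(benchmarkTable("small_ranks")[, -1]),
                             benchmarkTable("small_ranks")$model))
friedmanRankTest(rt)$statistic
#> [1] 14.42857
nemenyiCD(k = 6, n = 4, alpha = 0.05)
#> [1] 3.770196
averageRanks(rt)
#> CenterNet       SSD      FCOS    YOLOV5    YOLOV7      Ours
#>      3.75      5.00      3.50      5.25      2.50      1.00
```

The Friedman chi-square (14.429 > the 0.05 critical value, p ≈ 0.013)
says the six detectors differ significantly across P/R/F1/AP; the
proposed detector's average rank of 1.00 beats SSD and YOLOv5 by more
than the Nemenyi critical distance 3.770, so those gaps are
statistically significant.

A desk-scale end-to-end run — eight 64×64 synthetic scenes, anchors
clustered from the training boxes, 300 CPU epochs — overfits to
AP@0.5 ≈ 0.93 with a ~99 % loss reduction (see
`tests/testthat/test-acceptance.R`):

```r
scenes <- lapply(1:8, function(i)
  synthScene(sceneParams(imageSize = c(64, 64), nFaces = c(2, 2),
                         faceSideRange = c(12, 28), clusterProb = 0,
                         noiseSD = 0.01, seed = i)))
wh <- do.call(rbind, lapply(scenes, function(s)
  annotationBoxes(s$annotation)[, 3:4, drop = FALSE]))
model <- buildDetector(modelConfig(inputSize = 64, baseChannels = 8),
                       kmeansAnchors(wh, k = 9, seed = 1), seed = 1)
model <- trainDetector(model, scenes,
                       trainConfig(batchSize = 8, learningRate = 5e-3,
                                   epochs = 300, seed = 1))
evaluateDetector(model, scenes, iouThresh = 0.5)
#>      model         P      R        F1        AP
#> 1 detector 0.8823529 0.9375 0.9090909 0.9301471
```

A thin command-line wrapper ships in `inst/scripts/capridetect`
(`synth`, `train`, `evaluate`, `predict`, `compare`).

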
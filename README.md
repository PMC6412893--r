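# harsdae

Human activity recognition from smartphone inertial sensors with
**stacked denoising autoencoder (SDAE) features** and a **boosting
k-fold ensemble of gradient-boosted decision trees**.

`harsdae` is for researchers working on wearable/mobile sensing who
want an end-to-end, fully testable activity-recognition pipeline:
classifying locomotion (walking, stairs), static postures (standing,
sitting, lying) and vertical transport (elevators, escalators) from
multichannel accelerometer, gyroscope, magnetometer and barometer
recordings — without hand-engineering features and without needing any
external dataset to exercise the code.

## The method

1. **Preprocessing.** Each recording `X_k` of sensor `k` (dimension
   `d_k`) is cut into sliding windows of `w` samples with stride `s`
   (a window is emitted iff `start + w <= T`, giving
   `floor((T - w)/s) + 1` windows). Windows are flattened to vectors
   `x_i^k in R^(w d_k)` (axes interleaved within a timestamp) and
   min–max standardised per column with *training-set* extrema:
   `x' = (x - min)/(max - min)`. Test data reuses the training extrema
   and is not clipped.
2. **Unsupervised feature extraction.** One SDAE per sensor. Each
   layer corrupts its input by Bernoulli zero-masking at probability
   `theta_noi` (dropout 0.4 by default), encodes with a sigmoid affine
   map and decodes back, trained to minimise the MSE against the
   *clean* input. Layers are pretrained greedily on the clean
   encodings of the layer below, then the unrolled encoder–decoder is
   fine-tuned end-to-end on the same reconstruction objective. The
   learned features are the corruption-free encoder composition
   `e_i = f_enc(... f_enc(x_i; theta^1); ... theta^n)`, concatenated
   across sensors (e.g. three sensors x top width 30 = 90 features).
3. **Supervised classification.** *Boosting k-fold*: a stratified
   k-fold plan is processed sequentially; every sample misclassified
   in fold f's validation set is duplicated once into fold f+1's
   training set (the misjudged set is replaced each fold, not
   accumulated). Each fold trains a multiclass gradient-boosted tree
   model; test predictions are the majority vote of the k models, with
   ties broken toward the smallest class index.
4. **Diagnostics.** Class separability is measured by scatter-matrix
   traces: within-class `S_W(i) = (1/N_i) sum (x - m_i)(x - m_i)^T`,
   `S_W = sum_i P_i S_W(i)`, and between-class
   `S_B = 1/2 sum_ij P_i P_j (m_i - m_j)(m_i - m_j)^T`. Good features
   shrink `tr(S_W)` while keeping `tr(S_B)` large.

Also included: a single-SDAE + softmax baseline, a hand-crafted
(statistical/spectral) feature baseline, macro-averaged
precision/recall/F1 metrics, a reader for the public UCI smartphone
layout, and a synthetic IMU generator (gravity orientation + gait
harmonics + barometric drift) that emulates the class structure the
pipeline assumes.

## Worked example

```r
library(harsdae)

ds  <- simulate_har_dataset(duration = 10, recordings_per_class = 10, seed = 42)
fit <- har_pipeline(ds, schema_imu(50), window_len = 128, stride = 128,
                    sdae = sdae_config(c(100, 30), pretrain_epochs = 8,
                                       fine_tune_epochs = 8),
                    k = 5, seed = 42)
fit
#> Activity-recognition pipeline fit
#> Accuracy 0.9630 | macro P 0.9667 R 0.9630 F1 0.9628 (6 classes, 54 samples)
#> # A tibble: 2 × 3
#>   space    inner_trace outer_trace
#>   <chr>          <dbl>       <dbl>
#> 1 raw            49.8        36.2
#> 2 features        1.61        1.43
tidy(fit$model)
#> # A tibble: 5 × 4
#>    fold train_size val_size misjudged
#>   <int>      <int>    <int>     <int>
#> 1     1        100       26         1
#> 2     2        101       26         0
#> 3     3        102       24         2
#> 4     4        103       25         1
#> 5     5        102       25         0
```

60 recordings (6 activities x 10) of 10 s at 50 Hz yield 180 windows;
the held-out 30% (54 windows) is classified with 96.3% accuracy. The
divergence table shows the SDAE compressing the within-class trace
from 49.8 to 1.61 — classes become far more compact in feature space —
and the fold table shows the boosting bookkeeping: fold 2 trains on
its 100 base samples plus the 1 sample fold 1 misjudged.

`autoplot(fit$eval)` draws the confusion heatmap,
`autoplot(fit$stacks$acc)` the reconstruction-loss curves, and
`plot_feature_distribution(fit$features$train, 5)` the per-class
distribution of one learned feature.

A thin CLI wrapping the same functions lives at `inst/cli/harsdae.R`
(`simulate`, `pipeline`, `diagnose`, `baseline` subcommands).

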
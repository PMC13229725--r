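# attnseq

Hierarchical-attention classification of multimodal human-movement
sequences, with a planted-motif synthetic benchmark and an ablation
harness.

## The problem

In clinical movement analysis (gait assessment, posture screening, spinal
dysfunction workups), a recording pairs a video stream with wearable-sensor
channels, and the diagnostically informative signal is usually confined to a
short movement phase — one part of a gait cycle, one bending transition.
`attnseq` trains a sequence classifier that (a) fuses the two modalities,
(b) classifies the behaviour, and (c) exposes *where in time* the evidence
was, through normalized attention weights that can be scored against
annotated windows.

## The model

Each sample carries a per-frame video embedding stream (the package
consumes embeddings, never pixels) and a multi-channel sensor stream at its
own rate. The pipeline is:

* bidirectional tanh recurrent encoders per modality (1-D convolutions
  first on the sensor branch),
* late fusion by linear interpolation of the sensor embeddings onto the
  video frame times followed by concatenation: one fused row
  $h_t \in \mathbb{R}^{d_f}$ per frame,
* additive attention $e_t = v^\top\tanh(W_h h_t + b_h)$,
  $\alpha = \mathrm{softmax}(e)$, aggregated hierarchically: segment vectors
  $s_k = \sum_{t\in T_k}\alpha_t h_t$, segment weights
  $\beta = \mathrm{softmax}(u^\top\tanh(W_s s_k + b_s))$, representation
  $r = \sum_k \beta_k s_k$ (multi-scale windowed pooling and an
  expert-relevance score adjustment are configuration options),
* a two-layer softmax classifier head, trained with
  $L = L_{\mathrm{CE}} + \lambda \sum_t (\alpha_t - \alpha_{t-1})^2
  + w\lVert\theta_{\mathrm{attn}}\rVert^2$
  under Adam, cosine annealing, gradient clipping and parameter averaging
  (EMA). All gradients are analytic and finite-difference-checked.

The methods vignette (`vignettes/hierarchical-attention.Rmd`) documents the
design decisions, the synthetic generator, and known limitations.

## Worked example

```r
library(attnseq)

# 4-class planted-motif task: 240 training and 80 test recordings,
# 3 s each, motif 0.8 s at amplitude 1.5x the noise SD
train <- generate_dataset(synthetic_spec(n_per_class = 60, seed = 101), "train")
test  <- generate_dataset(synthetic_spec(n_per_class = 20, seed = 102), "test")

cfg <- attnseq_config(d_v = 16, d_s = 6, class_count = 4, seed = 1)
fit <- attnseq_fit(train, cfg)       # ~1 min on one CPU
report <- evaluate_model(fit, test)
report
#> <attnseq_report>  n = 80
#>   accuracy 0.9750 | macro P 0.9773 R 0.9750 F1 0.9753
#>   attention enrichment 2.787 over 80 annotated samples
#>   confusion (rows = truth):
#>      0  1  2  3
#>   0 20  0  0  0
#>   1  1 19  0  0
#>   2  0  0 20  0
#>   3  1  0  0 19

bayes_separability_probe(synthetic_spec(n_per_class = 20, seed = 103), 500)
#> [1] 1
```

The model recovers 97.5% of the test labels (the matched-filter oracle that
knows the true motifs achieves ~100%, so the learned model is within 2.5
points of the ceiling), and its attention places 2.8x more mass inside the
annotated motif window than a uniform profile would — the localization
signal that makes the classifier interpretable. `plot(fit, test$samples[[1]])`
draws the attention profile against the annotated window, and
`ablation_suite()` reproduces the component ablation table (full model vs.
video-only, mean pooling, and no temporal regularization) over several
seeds.

Datasets read and write as a JSON-Lines manifest plus per-stream CSV files
(`write_dataset()` / `read_dataset()`); models checkpoint to a single JSON
file (`save_checkpoint()` / `load_checkpoint()`). A thin command-line
wrapper with `simulate` / `train` / `evaluate` / `explain` / `ablate`
subcommands is installed at `inst/cli/attnseq-cli.R`.

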
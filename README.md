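# optconform

Simulation-based introspection of stochastic optimizers, and a desk-scale
transfer-learning evaluation for biological network-image classification.

## The problem

Deep transfer-learning classifiers for single-cell gene regulatory
network (SCGRN) images — distinguishing healthy controls from type 2
diabetes (T2D) subjects — work by freezing part of a pretrained
convolutional base and retraining the rest with a stochastic optimizer.
Why does the choice of optimizer matter so much? One interpretability
argument compares the *models that optimizers produce*: fit the same
data with different optimizers and measure how far apart the fitted
models are. `optconform` implements that argument end to end, for
researchers who want a reproducible, self-contained realization of the
protocol:

1. **Optimizer conformance study.** From-scratch SGD, RMSprop and Adam
   fit the linear model H(x) = θ₀ + θ₁x to data from four benchmark
   functions (a line, a saturating exponential, a parabola, and the
   classic multimodal surrogate benchmark (6x−2)² + sin(12x−4)), by
   minimising Q(θ) = (1/m)Σᵢ(θ₀+θ₁xᵢ−yᵢ)². Per run, the pairwise
   distance between fitted prediction sets

       d_AB = sqrt( Σᵢ [ (xᵢᴬ−xᵢᴮ)² + (zᵢᴬ−zᵢᴮ)² ] )

   is computed for SGD–Adam (d_SA) and SGD–RMSprop (d_SR); nine runs
   give two distance samples compared with a two-sided Welch t-test.
2. **Transfer evaluation.** A small 3-block CNN (pure R, gradient-checked)
   is pretrained on a synthetic multi-class source task, its densely
   connected classifier is replaced, and it is trained under TFe (whole
   convolutional base frozen), TFt (bottom blocks frozen) or from
   scratch, on a balanced 224-image synthetic SCGRN-style corpus.
   Predictions use the healthy-class score with a strict 0.5 threshold;
   balanced accuracy, accuracy, precision, recall and F1 (healthy =
   positive class) are reported under five-fold cross-validation with a
   combined confusion matrix.

Everything is generated: no external data, no pretrained weights. All
randomness flows through explicit seeds.

## A worked example

```r
library(optconform)

st <- run_conformance_study("F2", n_runs = 9, m = 100, base_seed = 1)
st
#> <conformance_study> F2: 9 runs, mean d_SA = 0.002898, mean d_SR = 0.006783, p = 0.0317
```

Nine times, a fresh 100-point dataset was drawn from
F2(x) = 1 − exp(−1/(2x)) and fitted with all three optimizers; the
Adam-fitted models sit about twice as close to the SGD-fitted models
(mean d_SA ≈ 0.0029) than the RMSprop-fitted ones do (mean d_SR ≈
0.0068), and the Welch test over the nine paired distances calls the
difference significant (p ≈ 0.03) — the conformance direction the
protocol is designed to detect.

```r
m <- compute_metrics(confusion_matrix(
  y_true = c(rep("healthy", 50), rep("T2D", 50)),
  y_pred = c(rep("healthy", 45), rep("T2D", 5),
             rep("T2D", 40), rep("healthy", 10))))
m
#> <metrics_report> BAC=0.8500 ACC=0.8500 PRE=0.8182 REC=0.9000 F1=0.8571
```

The full pipeline — regression datasets, optimizer fits, conformance
studies with figures, corpus generation, transfer evaluation — runs as
numbered drivers:

```sh
Rscript analysis/01_simulate_regression.R --seed 1 --out results/regression
Rscript analysis/02_fit_optimizers.R      --seed 1 --out results/fits
Rscript analysis/03_conformance_study.R   --seed 1 --out results/conformance
Rscript analysis/04_generate_corpus.R     --seed 1 --out results/corpus
Rscript analysis/05_transfer_eval.R       --seed 1 --out results/transfer
```

The methods vignette (`vignettes/optimizer-conformance.Rmd`) documents
the model, the protocol decisions and their rationale, and what the
synthetic corpus does and does not emulate.

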
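# ssdfrn

Self-supervised disturbing-feature reconstruction networks for
small-sample biomass regression.

## The problem

Mangrove aboveground biomass (AGB) campaigns yield a few dozen labelled
plots, while each plot carries a rich vector of remote-sensing
covariates — here 22 features: 7 Landsat-8 band values, 6 vegetation
indices (NDVI, RVI, DVI, SAVI, EVI, GNDVI), 8 GLCM texture statistics
and a topographic factor. Deep regressors overfit badly at that sample
size. `ssdfrn` implements a two-stage remedy:

1. **Disturbing-feature reconstruction pretraining.** For each sample a
   window of `W = 4` consecutive features at random position
   `P ~ U{1, ..., L-W-1}` is permuted and masked with additive Gaussian
   noise (*auxiliary data* x̃); the remaining `L - W = 18` features
   (*residual data*) enter a multi-view cascaded convolutional encoder
   (MVCNN). The encoder's projected representation is spliced with x̃ at
   position `P` and a small convolutional decoder must reconstruct the
   original vector, minimising the mean squared error over all `L`
   features. Fresh windows, permutations and noise every epoch make the
   self-supervised training set unlimited by the plot count.
2. **Fine-tuning.** A two-layer head (`18 → 200 → 1`) on the encoder's
   representation of the undisturbed feature vector is trained against
   squared biomass error, `mean((ŷ - y)^2)`.

The encoder's building block (MVCCM) runs three stride branches
(strides 1, 2, 3), each cascading small → medium convolutions (kernels
2, 3), concatenating their maps along the length axis, and applying a
large convolution (kernel 4); branch outputs are concatenated along the
length axis (16 kernels in module 1, 32 in module 2, max-pool 2/2
between modules). Plot labels follow the Kandelia allometry
`y = 3.614 · D^1.446` from near-ground branch trunk diameter `D`.

The field dataset behind the method is confidential, so the package
includes a synthetic generator: a latent canopy density drives
reflectance-like bands (NIR up, red/SWIR down), the indices are computed
from those bands by their standard formulas, and biomass follows the
allometric push-forward of a latent diameter, rescaled to the published
10–29 biomass-unit range. All networks (1-D convolutions, pooling,
backprop, Adam) are implemented in vectorized base R — appropriate for
the tens-of-samples regime this method targets.

## Worked example

```r
library(ssdfrn)

sp <- simulate_split(n = 58, seed = 1)   # 40 training / 18 test plots
fit <- ssdfrn_fit(sp$train,
                  train = train_config(epochs_stage1 = 200,
                                       epochs_stage2 = 200, seed = 1))
fit
#> <ssdfrn> biomass estimation model
#>   encoder: mvcnn | 2 module(s) | projection width 18
#>   pretrained: TRUE | frozen encoder: TRUE
#>   stage-2 epochs: 200 | final loss: 0.9932

evaluate_model(sp$test, fit)
#> <eval_report> test | n = 18 | MAE = 0.8441 | RMSE = 1.136
```

The fitted object records both loss histories (`tidy(fit)`,
`autoplot(fit)`): here stage-1 reconstruction loss fell from 1.01 to
0.36 and stage-2 biomass loss from 26.4 to 0.99 (squared biomass units)
over 200 epochs. The evaluation report says the estimator recovers
held-out biomass to within 0.84 biomass units on average (RMSE 1.14) on
plots spanning 10–29 units — the same error scale as the published
Kandelia results. `run_ablation()` repeats the comparison against a
no-pretraining variant and a plain-CNN encoder on seeded splits;
pretraining is the dominant ingredient (median MAE 0.95 with it, 2.88
without, over ten splits).

The package also ships the 18 published actual/estimated test pairs
(`reference_test_pairs()`); the metric code reproduces their published
summaries exactly (RMSE 1.396; MAE 1.1437 against the published 1.145,
which was averaged before rounding).

A command-line wrapper over the same functions is installed at
`inst/scripts/ssdfrn.R` (`simulate`, `pretrain`, `finetune`, `fit`,
`predict`, `evaluate`, `ablate`).

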
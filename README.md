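# diffage

Dual-guidance denoising-diffusion regression of **brain age** from 2D slices
of structural (T1-weighted) brain MRI, with the full surrounding pipeline:
intensity preprocessing and percentile slice selection, multi-slice
ensembling with outlier exclusion, and brain-age-gap statistics (volumetric
group comparisons, longitudinal rate categorisation, optional age-bias
correction). The package targets researchers studying brain development and
aging who want an implementable, testable diffusion-regression pipeline —
and, because real multi-site MRI cannot ship with a package, it includes a
synthetic phantom generator that encodes age geometrically so every
component runs and validates end to end at desk scale.

## The model

Ages are normalised to `y0 ∈ [-1, 1]` and corrupted by a DDPM forward
process with a linear schedule `β1 = 1e-4 … βT = 0.02`:

    y_t = sqrt(ᾱ_t) y0 + sqrt(1 − ᾱ_t) ε,   ᾱ_t = ∏_{s≤t} (1 − β_s)

A conditional denoiser `ε_θ(ρ(x), y_t, ŷ^g, ŷ^l, t)` — a multilayer
perceptron over the image embedding, the noised response, two guidance
priors, and a timestep embedding — is trained with

    L_diff = L_e + ½ (L_MMD^g + L_MMD^l),    L_e = ‖ε − ε_θ(·)‖²

where the two regularisers are maximum-mean-discrepancy distances between
noise predictions under single-prior conditioning and standard-normal
reference draws. The **global prior** `ŷ^g` is the mean of a saliency map
from a convolutional encoder; the **local prior** `ŷ^l` pools
top-k saliency regions of interest through a gated-attention mechanism.
Prediction runs the ancestral reverse chain from `y_T ~ N(0,1)` (σ_t² = β_t),
averages several chains, and maps back to years. Per-subject consensus
averages the per-slice models after excluding predictions more than one
sample standard deviation from the ensemble mean.

All networks (residual convolutional encoders, gated attention, denoiser)
and their backward passes are implemented in plain R with BLAS matrix
products — no deep-learning framework is required.

## Worked example

Train a single-slice model on 400 synthetic phantoms and evaluate on 100
held-out phantoms (about a minute on one CPU):

```r
library(diffage)

spec  <- phantom_spec()                      # 32^3 phantoms, ages 3-30
train <- generate_cohort(400, spec, seed = 1)
test  <- generate_cohort(100, spec, seed = 3)

train_slices <- cohort_slice_table(train, percentiles = 50)
test_slices  <- cohort_slice_table(test,  percentiles = 50)

model <- train_diffage(train_slices,
                       training_config(max_epochs = 20, batch_size = 64,
                                       seed = 1))
model
#> <diffage_model> T = 100 | slices 32x32 | best epoch 18 | val loss 0.5706

preds <- predict(model, test_slices, seed = 9)
mae_iqr(preds)
#> # A tibble: 1 × 4
#>     mae iqr_lo iqr_hi     n
#>   <dbl>  <dbl>  <dbl> <int>
#> 1  1.97  0.898   2.85   100
round(cor(preds$predicted_age, preds$age), 3)
#> [1] 0.96
```

The held-out mean absolute error of about 2 years (against a ~6.8-year
mean-predictor baseline for uniform ages on 3-30) and a predicted-vs-true
correlation of 0.96 show the model recovering the phantom age encoding from
images alone. `tidy(model)` returns the per-epoch loss breakdown,
`autoplot(model)` plots the training curves, `plot_predictions(preds)` the
scatter, and `plot_saliency(model, test_slices$slice[[1]])` the guidance
saliency map with its selected ROIs.

The full pipeline (simulate → preprocess → train five slice models → predict
→ ensemble → evaluate, with stage caching and provenance logging) is one
call:

```r
res <- run_pipeline(validate_config(list(seed = 1, n_train = 2000,
                                         n_val = 200, n_test = 200)))
res$report
```

A thin command-line interface over the same functions is installed at
`inst/cli/diffage.R` (subcommands `simulate`, `preprocess`, `train`,
`predict`, `ensemble`, `evaluate`, `run`).

## Package layout

- `R/phantom.R` — synthetic phantom, cohort, volumetric, longitudinal generators
- `R/preprocess.R` — isotropic rescale, Otsu background removal, median
  filtering, valid-slice detection, percentile slice selection
- `R/nn.R`, `R/train.R` — networks, backprop, Adam, the joint trainer
- `R/diffusion.R`, `R/dcg.R`, `R/losses.R` — schedule, forward/reverse
  processes, dual-granularity guidance, noise/MMD losses
- `R/ensemble.R`, `R/analysis.R` — slice ensembling and gap statistics
- `R/interface.R`, `inst/cli/diffage.R` — config validation, pipeline,
  provenance, CLI
- `vignettes/diffusion-brain-age.Rmd` — the methods vignette
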
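# skipgru

Clinical tabular risk classification with a skip-gated recurrent unit
(Skip-GRU) trained under clip-by-norm gradient clipping, plus the full
pipeline around it: zero-coded missing-value handling by
polynomial-regression imputation, min–max normalization, wrapper feature
selection by a random-spiral-flight marine predator algorithm (RSFS–MPA),
and stratified k-fold evaluation with confusion-matrix metrics.

The package targets the diabetes-screening setting — tables like the PIMA
Indian diabetes layout (768 patients × 8 clinical features, 2 classes) or
a hospital laboratory layout (~12 features, 3 imbalanced classes) — but
every component is generic over numeric features and class labels. A
synthetic-data module generates tables with the same statistical structure
(planted informative features, zero-coded missingness, class imbalance),
so the whole pipeline is testable without any external download.

## The model

**Preprocessing.** Features rescale to [0, 1] by
`(x − x_min)/(x_max − x_min)`. Columns where the value 0 encodes a missing
measurement are declared explicitly; per column, a missing fraction
strictly above 5% is imputed by least-squares polynomial regression
(default degree 2) on the other features, while a positive fraction at or
below 5% drops the affected rows.

**Feature selection.** RSFS–MPA searches the continuous unit box and
decodes positions into feature subsets by thresholding at 0.5. Movement
follows the three-phase marine predator schedule (Brownian exploration,
mixed Lévy/Brownian transition, Lévy exploitation) with the adaptive
factor `A = (1 − t/T)^(2t/T)`, FADs long jumps with probability 0.2, and a
random spiral update `prey + e^(zL)·cos(2πL)·|elite − prey|` with
`z = e^(k·cos(π(1 − t/T)))` during exploration. Subsets are scored by
`0.99·CVerr + 0.01·|m|/d`, where CVerr is the stratified CV error of a
fast naive Bayes surrogate on the masked features.

**Classifier.** Each selected feature is one timestep of a GRU. A two-layer
jump gate computes a keep probability
`π_t = softmax(W₂·ReLU(W₁[x_t; h_{t−1}] + b₁) + b₂⁽ᵗ⁾)`; at inference,
`π_t < 0.5` skips the feature and carries the state over exactly
(`h_t = h_{t−1}`), while training uses the differentiable relaxation
`h_t = π_t·GRU(x_t, h_{t−1}) + (1 − π_t)·h_{t−1}`. Training is Adam
(lr 1e-4, decoupled weight decay 0.1, dropout 0.3, batch 32) with
clip-by-norm at every step: if the global gradient norm exceeds
`η_c = 1`, the whole gradient collection is rescaled by `η_c/‖∇‖`,
preserving direction. Mean keep probabilities per feature
(`gate_importance()`) expose which features the model actually consumes.

**Evaluation.** Accuracy, sensitivity, precision, specificity and F1 (in
percent) from one-vs-rest confusion counts; binary reports use the
positive class, multiclass reports macro-average. Stratified k-fold
cross-validation (default k = 5) refits imputation and normalization
inside every training fold.

## Worked example

```r
library(skipgru)

spec <- synthetic_presets()[["pima-like"]]   # 768 x 8, two classes
gen  <- generate_synthetic(spec, seed = 42)
ds   <- gen$dataset
ds
#> <tabular_dataset> 768 samples x 8 features, 2 classes
#>   classes: class0 (n=508), class1 (n=260)
#>   zero-coded missing columns: glucose, blood_pressure, skin_thickness, insulin, bmi

# impute (>5% missing) or drop rows (<=5% missing), then normalize
imp <- impute(ds, pipeline_config(seed = 42))
imp$report$features$insulin$action          # "impute" (45% missing)
nrow(imp$dataset$features)                  # 715 rows kept
treated <- imp$dataset; treated$missing_columns <- character()
dn <- apply_minmax(treated, fit_minmax(treated))

# wrapper feature selection
fs <- select_features(dn, mpa_config(n_pop = 15, max_iter = 30), seed = 42)
fs
#> <fs_result> 6/8 features selected, fitness 0.0615
#>   selected: glucose, blood_pressure, insulin, bmi, pedigree_function, age

# the preset plants glucose, insulin, bmi, pedigree_function, age as
# informative -- all five are recovered (blood_pressure is a false positive)

# cross-validated Skip-GRU on the selected subset
cv <- kfold_evaluate(ds,
        pipeline_config(seed = 42, cv_k = 5,
          model = skipgru_config(hidden_size = 32, gate_hidden = 8,
                                 epochs = 40, learning_rate = 1e-3)),
        mask = fs$mask)
cv
#> <cv_result> k = 5 (seed 42)
#>   accuracy      90.36% +/- 2.62
#>   sensitivity   88.85% +/- 3.94
#>   precision     84.12% +/- 6.15
#>   specificity   91.15% +/- 4.16
#>   f1            86.26% +/- 3.35
```

The CV numbers are what a 40-epoch, hidden-32 network reaches on this
synthetic table; they measure the pipeline's mechanics on planted
Gaussian structure, not performance on real clinical data.

A command-line wrapper over the same functions ships at
`inst/cli/skipgru.R` (after installation:
`system.file("cli", "skipgru.R", package = "skipgru")`), with subcommands
`simulate`, `preprocess`, `select-features`, `train`, `evaluate`.

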
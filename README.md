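# pfec

Pulse feature-enhanced classification (PFEC) of single-particle polarized
light scattering and fluorescence signals, for rapid optical monitoring of
phytoplankton and cyanobacteria in water (e.g. harmful-algal-bloom
surveillance in aquaculture).

A flow-through instrument illuminates one particle at a time with
polarized laser light and splits the backscattered light into four
polarization channels plus one fluorescence channel. Each particle transit
produces a five-channel pulse. This package implements the complete
analysis chain from raw pulse trains to sample-composition reports, plus a
synthetic instrument simulator so that every stage can be exercised and
tested without instrument data.

## The method

**Stokes calibration.** The measured polarization components
`[I1, I2, I3, I4]ᵀ` are mapped to the Stokes vector by the instrument
matrix `A`:

    S = (I, Q, U, V)ᵀ = A · (I1, I2, I3, I4)ᵀ

`A` is estimated from calibration measurements pairing reference Stokes
states (from a reference polarimeter) with measured components,
`A = S_ref · M⁺`, the least-squares solution over all states (plain matrix
inverse when exactly four states are used). The normalized components are
`q = Q/I`, `u = U/I`, `v = V/I`, and the degree of polarization is
`DOP = sqrt(q² + u² + v²)` ∈ [0, 1].

**Pulse features.** Each particle's Stokes-domain traces `I, q, u, v`
yield eight statistics apiece — peak-to-peak, variance, standard
deviation, RMS (population moments), skewness, kurtosis, waveform factor
(RMS/mean) and clearance factor (peak-to-peak/mean², exactly as defined in
the instrument's feature table) — which, with the six pulse averages
`(Ī, q̄, ū, v̄, DOP, F)`, form the 38-dimensional PFEC feature vector. The
6-dimensional averages-only vector is the pulse-average classification
(PAC) baseline.

**Classification.** A backpropagation neural network with five hidden
layers (64-128-256-128-64, ReLU, softmax cross-entropy, Adam, early
stopping) is trained on a stratified 60/20/20 train/validation/test split
and evaluated by confusion matrix and overall accuracy. Per-particle
predictions are aggregated into per-sample category proportions,
renormalized to the three phyla after removing non-algal particles, and
screened for dominant (> 10 % of microalgae + cyanobacteria) and common
(1-10 %) species; Pearson's `r` quantifies association with reference
measurements.

## Worked example

```r
library(pfec)

# 1. simulate a raw stream from the built-in four-category panel
panel  <- demo_panel()
stream <- simulate_stream(panel, duration = 100000, arrival_rate = 0.002,
                          noise_level = 0.02, seed = 1)
nrow(stream_truth(stream))
#> [1] 191

# 2. calibrate the instrument matrix from 8 reference states
A_true <- default_instrument_matrix()
cal <- simulate_calibration_set(A_true, n_states = 8, noise_level = 0.005,
                                seed = 2)
A <- estimate_instrument_matrix(cal)
A
#> <instrument_matrix>  condition number 3.253, estimated from 8 states
#>         I1       I2       I3       I4
#> I  1.00306  1.00385 -0.00308 -0.00321
#> Q  0.99361 -1.00617  0.00279  0.00440
#> U -1.00140 -1.00398  1.99899 -0.00322
#> V -1.01454 -1.01578  0.00656  2.02520

# 3. segment pulses, convert to Stokes traces, extract the 38 features
pulses   <- detect_pulses(stream) |> match_truth(stream_truth(stream))
traces   <- stokes_traces(pulses, A)
features <- pfec_features(traces)
dim(features)
#> [1] 189  40     # 38 features + QC count + label

# 4. train and evaluate the classifier
split <- split_dataset(features, seed = 3)
model <- train_classifier(split, mlp_config(epochs = 100, seed = 4))
test  <- dplyr::filter(split, .split == "test")
evaluate(test$label, predict(model, test), classes = model$classes)
#> <pfec_confusion>  overall accuracy 100.00% on 37 particles

# 5. sample composition and three-phyla renormalization
preds <- tibble::tibble(sample_id = "site-1", label = predict(model, features))
comp  <- summarize_composition(preds)
renormalize_phyla(comp, drop = "other_SPM")
#> # A tibble: 3 × 4
#>   sample_id category            n proportion
#> 1 site-1    Bacillariophyta    39      0.283
#> 2 site-1    Chlorophyta        48      0.348
#> 3 site-1    Cyanophyta         51      0.370
```

The recovered instrument matrix sits within ~1 % of the ideal analyzer
(whose rows are `(1,1,0,0)`, `(1,-1,0,0)`-type combinations), detection
finds 189 of the 191 injected particles, and the four synthetic
categories — which differ in mean Stokes response, pulse shape and
fluorescence — are fully separable at this noise level. `autoplot()`
methods display streams, confusion matrices and compositions;
`compare_pac_pfec()` runs the 38-feature and 6-feature classifiers on
identical partitions and reports the accuracy gain.

A command-line interface over the same pipeline is installed at
`inst/cli/pfec` (subcommands `simulate`, `calibrate`, `extract`, `train`,
`classify`, `report`, driven by a YAML configuration).

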
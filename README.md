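# dscpattern

Temporal-pattern analysis of dynamic susceptibility contrast (DSC) MRI
perfusion curves: autoencoder representation learning, k-means temporal
clustering, tissue characterization by pattern frequencies, and
dominant-cluster CNN classification of brain tumor type.

## Who this is for

Researchers analyzing DSC perfusion time series who want more than scalar
summaries. Standard processing reduces each voxel's 60-point time–signal
intensity curve to one number — relative cerebral blood volume (rCBV),
essentially the integral of the relaxation-rate change
ΔR₂\*(t) = −ln(S(t)/S₀)/TE — and discards the curve's shape: baseline
level, slope and depth of the bolus-induced signal drop, and the
percentage of the drop recovered by the end of acquisition. Those shape
features separate tumor types that scalar rCBV cannot (metastasis shows
very low percentage signal recovery, lymphoma high, glioblastoma is
heterogeneous).

## The method

For voxel curves \(x \in \mathbb{R}^{60}\), normalized to the patient's
pooled white-matter median and filtered by a ±1 SD mean-signal outlier
rule:

1. **Autoencoder.** A 1D convolutional encoder (kernel 2, 32 filters,
   "same" padding, ReLU, max-pool 2, batch-norm, dropout 0.7) maps each
   curve to a 5-dimensional latent code \(z = f(x)\); a two-layer
   fully-connected decoder \(g\) reconstructs the curve, trained by MSE
   \(\lVert g(f(x)) - x \rVert^2\).
2. **Temporal patterns.** k-means (k = 9, k-means++, 10 restarts) on the
   latent codes; decoding each centroid gives nine prototype curves.
   Cluster ids are canonically ordered by prototype nadir depth.
3. **Tissue characterization.** For each tissue class (or lesion), the
   percentage of its voxels in each pattern; rows sum to 100.
4. **Dominant-cluster CNN.** Inside a contrast-enhancing lesion the two
   highest-proportion patterns are the *dominant clusters*; the decoded
   curves of their voxels train a 1D CNN (3 conv blocks of kernel-2 ×
   32 maps with pool/2, batch-norm, dropout 0.7; 2 FC layers; softmax)
   that classifies tumor type. Voxel probabilities are averaged into a
   patient-level prediction.
5. **Evaluation.** AUC (Mann–Whitney), Youden-optimal sensitivity and
   specificity, stratified bootstrap 95% CIs, and DeLong's test for paired
   AUCs against an uncorrected rCBV-like comparator.

Both networks are implemented in the package (R + compiled C++ kernels)
with hand-written backpropagation, verified against finite-difference
gradients in the test suite. A gamma-variate digital phantom generator
with known per-voxel ground truth stands in for patient data.

## Worked example

```r
library(dscpattern)
library(dplyr)

# a labeled phantom: 9 tissue classes, 60 timepoints at 1.7 s
ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 4), seed = 7))
ph
#> DSC digital phantom: 16 x 16 x 4 voxels, 60 time points (dt = 1.7 s)
#> labeled voxels: 1024 across 9 tissues

curves <- extract_curves(ph$signal, ph$labels, patient_id = "demo") |>
  normalize_to_white_matter() |>
  remove_outliers()
round(attr(curves, "normalization_factor"), 2)
#>  demo
#> 98.45

# the pooled white-matter median is the normalization factor: after
# division every curve is in units of "white-matter signal", so ~0.5 for
# deep bolus nadirs, ~2 for bright CSF/necrosis baselines

cfg <- ae_config(learning_rate = 2e-3, batch_size = 2500, epochs = 300,
                 decoder_hidden = 64, polish_epochs = 400, seed = 1)
pipe <- run_pattern_pipeline(curves, config = cfg, k = 9, seed = 1)
pipe$frequency |> select(tissue, n_voxels, cluster_0, cluster_1, cluster_2)
```

Each row of `pipe$frequency` is a tissue's pattern profile in percent
(rows sum to 100); on a pure phantom each tissue concentrates in one
cluster, mirroring the "dominant pattern per tissue" structure seen in
patient studies. `autoplot(pipe$clusters)` draws the nine decoded
prototype curves; `build_cluster_map()` + `write_cluster_map()` put the
assignments back on the voxel grid as a NIfTI volume.

Dominant-cluster selection on a lesion's frequency row:

```r
row <- setNames(c(13.5, 0.3, 14.3, 26.7, 4.6, 32.6, 1.4, 2.3, 4.3),
                paste0("cluster_", 0:8))
select_dominant_clusters(row)
#> # A tibble: 2 × 2
#>   cluster percentage
#>     <int>      <dbl>
#> 1       5       32.6
#> 2       3       26.7
```

## Package layout

- `R/archetypes.R`, `R/phantom.R` — synthetic curve model and phantom
- `R/preprocess.R` — curve extraction, normalization, outlier rule
- `R/nn.R`, `src/nn_kernels.cpp` — network primitives (compiled)
- `R/autoencoder.R`, `R/clustering.R`, `R/spatial_map.R` — representation
  learning, temporal patterns, anatomic mapping
- `R/classify.R` — dominant clusters and the CNN
- `R/evaluate.R` — ROC/AUC, DeLong, confusion metrics, rCBV comparator
- `vignettes/temporal-patterns.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
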
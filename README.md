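# spectraqsar

Does a GC-EI-MS measurement — the full-scan electron-ionization mass
spectrum plus the Kovats retention index (RI) — carry enough structural
information to support QSAR/QSPR modelling, without ever resolving the
structure? `spectraqsar` implements the full analysis pipeline for that
question: it builds *analytical descriptors* (unit-mass binned spectra
concatenated with RI) and *molecular descriptors* (circular fingerprints,
MACCS and PubChem-style structure keys, continuous topological
descriptors), embeds compounds with an exact from-scratch t-SNE, compares
within- and between-cluster cosine similarity of standardized spectra,
benchmarks gradient-boosted property/toxicity regressions across
descriptor types, and fits linear models on six spectral summary
indicators (`center_mz`, `maxint_mz`, `max_mz`, `sd_mz`, `bin_num`, RI).

Commercial spectral libraries cannot be redistributed, so the package
ships a seeded synthetic-spectrum generator whose scaffold families
(PCB-like chlorination ladder, n-alkanes, alkylbenzenes, aliphatic
esters) reproduce the statistical regimes the analysis depends on:
homologous series with pattern-similar but mass-shifted spectra,
retention indices correlated with size and polarity, class labels, and
properties drawn from stated linear structure–property models.

## The core quantities

t-SNE minimizes the Kullback–Leibler loss between pairwise affinities in
descriptor space and on the 2-D map,

L = Σᵢⱼ pᵢⱼ log(pᵢⱼ/qᵢⱼ),  pᵢⱼ = (p_{i|j} + p_{j|i}) / 2n,

with Gaussian conditional affinities p_{j|i} whose bandwidths σᵢ are
calibrated by binary search so each row's perplexity 2^H equals the
target (default 30), Student-t map affinities
qᵢⱼ ∝ (1 + ‖yᵢ − yⱼ‖²)⁻¹, and momentum gradient descent on the exact
dense gradient 4Σⱼ(pᵢⱼ−qᵢⱼ)(yᵢ−yⱼ)(1+‖yᵢ−yⱼ‖²)⁻¹. QSAR models are
XGBoost regressions (300 trees, depth 6, η = 0.1, subsample 0.8);
performance is RMSE/MAE on the pooled validation + test compounds of a
seeded 70/15/15 split shared across descriptor kinds.

## Worked example

```r
library(spectraqsar)

d  <- generate_dataset(generator_config(n_compounds = 1000, seed = 1))
dm <- build_analytical_matrix(d)                     # 1000 x 567 bins + RI

sp  <- split_dataset(d, property = "log_mw", seed = 1)
lab <- setNames(d$log_mw, d$compound_id)
fit <- train_qsar(dm, lab, sp$compound_id[sp$split == "train"],
                  property = "log_mw")
rep <- evaluate_qsar(fit, dm, lab, sp$compound_id[sp$split != "train"])
glance(rep)
#> # A tibble: 1 x 7
#>   property descriptor_kind    rmse     mae r_squared n_train n_eval
#>   <chr>    <chr>             <dbl>   <dbl>     <dbl>   <int>  <int>
#> 1 log_mw   analytical      0.00662 0.00216     0.998     700    300
```

A held-out RMSE of 0.0066 log units (R² = 0.998) on log₁₀ molecular
weight shows the boosted model reading the molecular-ion position
straight out of the binned spectrum. The same pipeline contrasts
descriptor families on a homologous series:

```r
lad <- generate_homolog_ladder(scaffold_name = "pcb_like",
                               substituent_counts = 1:10, replicates = 5,
                               intensity_noise_cv = 0.05, seed = 1)
hc <- homolog_contrast(lad)
hc
#> # homolog_contrast: 9 adjacent pairs; mean Tanimoto 0.404 vs mean
#> #   spectral cosine 0.0487 ; map split k 3.8 vs 8
```

Adjacent chlorination homologs look alike to a circular fingerprint
(mean Tanimoto 0.40) but nearly orthogonal to the binned spectrum (mean
cosine 0.05), while the analytical t-SNE map still separates lightly
from heavily chlorinated congeners (cluster mean chlorine numbers 3.8
vs 8.0). `autoplot()` methods draw the maps; `plot_error_overlay()`
layers per-compound absolute prediction error onto them.

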
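---
title: "Analytical-descriptor QSAR from GC-EI-MS spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical-descriptor QSAR from GC-EI-MS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spectraqsar)
```

## The question and the two descriptor families

Electron ionization fragments a molecule into many ions; the resulting
unit-mass spectrum, together with the Kovats retention index (RI), is a
cheap, structure-free measurement available for every peak a non-target
GC-EI-MS screen detects. The package asks how much *structural*
information that measurement retains, by running the same clustering and
regression machinery over two descriptor families:

* **Analytical descriptor** — the spectrum binned onto a global
  unit-mass grid (default 35–600 u, round-half-up nominal masses,
  base-peak normalized to 999 following library convention), with RI
  appended as a final column. A variant without RI isolates the
  contribution of retention information.
* **Molecular descriptors** — computed from SMILES: a radius-3 circular
  (Morgan) fingerprint hashed to 1024 bits, the 166-bit MACCS key, an
  881-bit PubChem-layout substructure key, and a continuous
  topological/constitutional descriptor vector (molecular weight, logP,
  molar refractivity, TPSA, H-bond counts, ring/heteroatom/branch
  counts, Wiener index).

Standardization convention: descriptors are z-scored per column before
t-SNE (and the continuous topological variables likewise), but boosted
models consume the raw matrices — tree splits are invariant to monotone
rescaling, so standardizing there would change nothing. Constant columns
standardize to all-zero rather than being dropped, keeping feature
indices stable between training and evaluation.

## The embedding

`fit_tsne()` is an exact, dense t-SNE. Inputs are PCA-reduced to 30
components; Gaussian conditional affinities receive per-point bandwidths
from a binary search that matches each row's perplexity `2^H` to the
target (default 30) within 10⁻⁶ bits; the joint affinities are
`(P + Pᵀ)/2n`; map affinities use the Student-t kernel normalized over
all pairs; and the map follows plain momentum gradient descent
(learning rate 200, momentum 0.5 until iteration 250 then 0.8, 1000
iterations). The loss is recorded every iteration. There is no
Barnes–Hut approximation: at the problem sizes used here (hundreds of
compounds) the dense formulation is fast, and every intermediate — the
conditional matrix, the joint affinities, the gradient — is testable
against brute-force double loops and finite differences.

Numerical choices worth knowing:

* The bandwidth search shifts distances by the row minimum before
  exponentiating, so tight clusters cannot underflow the kernel.
* Map affinities are floored at 10⁻¹² to keep the loss finite.
* Early exaggeration (multiplying P for an initial stretch) is
  available but off by default, so the recorded trace is the true loss
  throughout a run.
* Initialization is a seeded small-variance Gaussian by default. A
  deterministic PCA initialization (`init = "pca"`) is provided for
  analyses where the *global* arrangement matters: plain momentum
  descent on data made of well-separated clumps is chaotic — we observed
  one-ulp initialization differences flipping the final configuration —
  and starting from the leading principal components preserves the
  large-scale gradient the map is asked about.

## Cluster similarity and class composition

`similarity_summary()` computes mean pairwise cosine similarity of the
standardized spectra within each map cluster, between every cluster
pair, and within each chemical class. The RI column is excluded:
similarity concerns the spectrum. Cosine of standardized vectors is
reported as a *similarity* (it is legitimately negative for
anti-correlated profiles); singleton clusters report `NA` rather than a
fabricated zero. Clusters come from k-means on the map (10 restarts,
seeded) or from a user-supplied label table, since reference analyses
often circle clusters by hand.

## QSAR benchmarking and the six indicators

`compare_descriptors()` trains one XGBoost regression per
(property, descriptor) pair — 300 trees, depth 6, learning rate 0.1,
row subsample 0.8, single-threaded for reproducibility — on a seeded
70/15/15 largest-remainder split shared across descriptor kinds for the
same property, evaluating on the pooled validation + test compounds.
The split protocol and hyperparameters are reproducible defaults, not a
tuned configuration; no grid search is performed.

`compute_indicators()` reduces each binned spectrum to six summary
statistics: the intensity-weighted mean and standard deviation of m/z
(`center_mz`, `sd_mz`; unweighted variants behind a flag), the m/z of
the most intense bin (`maxint_mz`, ties to the lowest m/z), the highest
occupied bin (`max_mz`), the occupied-bin count (`bin_num`, no
intensity threshold), and RI. All six are invariant to uniform
intensity rescaling. `fit_ols()` fits ordinary least squares through
the QR decomposition and reports rank deficiency as an error naming the
collinear columns; `indicator_comparison()` assembles the full design:
boosted analytical models with and without RI against the all-six and
single-variable linear models.

## What the synthetic generator emulates

`generate_dataset()` draws compounds from four fragmentation scaffolds —
a PCB-like chlorination ladder (+34 u per Cl, sequential 35-u losses, a
15-member biphenylene-core ion series), n-alkanes (+14 u, 43/57/71/85
series, base peak in the fragment series as in real paraffin spectra),
alkylbenzenes (91/77/65), and methyl esters (74/59/43) — with closed
SMILES templates so cheminformatics parsing always succeeds. Defaults
are the package's study conditions: 1000 compounds, equal scaffold mix,
substituent counts uniform on 0–8, multiplicative log-normal intensity
noise with CV 0.15, and `RI = 7·mass + 100·aromatic + N(0, 15)` (about
100 index units per CH₂, in the Kovats range 700–3500).

Three design features carry the structural signal the analyses probe:

* **Compound-specific minor fragments.** Real spectra contain many weak
  rearrangement peaks whose positions are a fixed, irregular property of
  the molecule. They are generated from a deterministic
  linear-congruential sequence keyed on (scaffold, substituent count),
  so replicates share them while `bin_num` varies irregularly between
  molecules instead of counting substituents.
* **Branching-ratio drift.** Characteristic-fragment intensities fall
  off as `1/(1 + 0.25k)` along a homolog series, as charge retention
  shifts toward heavier fragments with growing substitution. After
  standardization these shared columns carry a graded homolog signal.
* **Substituent effects on properties.** Property models are linear in
  (nominal mass, substituent count, aromatic flag) with Gaussian noise;
  log₁₀ molecular weight is exact by definition. The substituent-count
  coefficients matter: the same nominal mass arises from different
  scaffold/substituent combinations, so this component is readable from
  the full fragmentation pattern but not from any linear function of the
  six indicators. That asymmetry is what lets the full-spectrum boosted
  model dominate every indicator regression, while each property still
  has a characteristic dominant indicator (the molecular-ion position
  for log Mw, the retention index for boiling point).

What the generator does **not** emulate — isotope clusters, physically
derived fragmentation chemistry, condition-dependent RI shifts,
correlated property errors — bounds what passing tests show: the
pipeline's statistics behave correctly under the stated regimes, not
that any particular accuracy will transfer to a real spectral library.

## The homolog-contrast analysis

`homolog_contrast()` packages the homologous-series study: adjacent
chlorination homologs are structurally almost identical
(circular-fingerprint Tanimoto ≈ 0.3–0.5) while their binned spectra are
nearly orthogonal (cosine ≤ 0.15), because every fragment shifts with
the molecular ion. The analytical t-SNE map of a 50-spectrum ladder is
asked whether it still grades chlorination: here the embedding uses PCA
initialization, perplexity 20, learning rate 30 and early exaggeration
(×4 for 250 iterations). These settings were chosen for stability of the
global arrangement: the ladder is ten tight replicate clumps whose
mutual distances differ only through the graded core-series and RI
columns, a regime where the default map settings are chaotic. The
separation is summarized by the mean substituent count of the two
k-means map clusters and by agreement with the ladder-midpoint split; a
perfect threshold partition is not a robust property of maps of
near-orthogonal clumps and is not asserted.

## Problem sizes and determinism

Analyses in the tests and the acceptance script run at n = 1000
compounds for the regression benchmarks, n = 300 for map clustering,
n = 60 for optimizer diagnostics, and a 50-spectrum ladder for the
homolog contrast — sizes at which the dense t-SNE and the boosted models
complete in seconds to a few minutes on one core. Every stochastic step
(generation, splits, map initialization, k-means restarts, boosting
subsampling) is seeded; rerunning any entry point with the same seed
reproduces its output exactly.

## Known limitations

* The Morgan fingerprint's hash is package-specific: bit patterns are
  comparable within the package but not bit-for-bit with other
  toolkits (similarity values agree closely in practice).
* The 881-bit substructure key populates a documented subset of the
  PubChem layout; it is a stand-in key, clearly tagged in the matrix
  provenance, not the reference implementation.
* OLS on indicators can be exactly rank-deficient in small samples
  (e.g. when `max_mz` and `maxint_mz` coincide for every training
  compound); the fit refuses with an informative error rather than
  silently pivoting.
* Dense t-SNE scales quadratically; beyond a few thousand compounds a
  Barnes–Hut implementation would be needed.
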
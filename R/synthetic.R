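#' Built-in fragmentation scaffolds
#'
#' Four scaffold families spanning the regimes the pipeline probes:
#' a PCB-like chlorination ladder (aromatic homolog series, +34 u per Cl),
#' an n-alkane CH2 ladder with the 43/57/71/85 acylium-style fragment
#' series, a monosubstituted benzenoid with 91/77/65 tropylium-style
#' fragments, and an aliphatic methyl-ester family with 74/59/43 fragments.
#' Every scaffold emits its molecular ion, one peak per sequential
#' substituent neutral loss, and its fixed characteristic fragments; the
#' molecular ion carries the highest expected intensity except for the
#' alkane family, whose base peak sits in the fragment series as it does
#' in real paraffin spectra. The PCB-like scaffold carries the
#' biphenylene-core ion series (50--153 u) every chlorination level
#' shares, with branching ratios that fall off as chlorination grows.
#'
#' @return Tibble with one row per scaffold: `name`, `base_mass` (u of the
#'   unsubstituted skeleton), `substituent_mass` (nominal mass added per
#'   substituent), `loss_mass` (nominal mass of the sequential neutral
#'   loss), `mol_ion_weight`, `loss_weight`, `loss_decay`, `fragments`
#'   (list-column of `(mz, weight)` tibbles), `frag_k_decay` (the
#'   characteristic-fragment intensities fall off as `1 / (1 + decay * k)`
#'   with substituent count `k`, emulating the drift of fragment branching
#'   ratios along a homolog series), `superclass`, `class`, `aromatic`,
#'   `max_substituents`.
#' @export
default_scaffolds <- function() {
  tibble::tribble(
    ~name, ~base_mass, ~substituent_mass, ~loss_mass, ~mol_ion_weight,
    ~loss_weight, ~loss_decay, ~frag_k_decay, ~fragments, ~superclass,
    ~class, ~aromatic, ~max_substituents,
    "pcb_like", 154L, 34L, 35L, 1.0, 0.50, 0.75, 0.25,
    list(tibble::tibble(
      mz = c(50, 51, 63, 74, 75, 76, 85, 86, 98, 110, 111, 150, 151, 152, 153),
      weight = c(0.06, 0.10, 0.05, 0.08, 0.10, 0.22, 0.05, 0.04, 0.05, 0.06,
                 0.08, 0.10, 0.14, 0.28, 0.07))),
    "Benzenoids", "Biphenyls and derivatives", TRUE, 10L,
    "alkane_like", 114L, 14L, 14L, 0.85, 0.45, 0.75, 0.12,
    list(tibble::tibble(mz = c(43, 57, 71, 85), weight = c(0.80, 0.55, 0.40, 0.25))),
    "Hydrocarbons", "Alkanes", FALSE, 10L,
    "alkylbenzene", 92L, 14L, 14L, 1.0, 0.45, 0.75, 0.12,
    list(tibble::tibble(mz = c(91, 77, 65, 51), weight = c(0.60, 0.30, 0.15, 0.08))),
    "Benzenoids", "Benzene and substituted derivatives", TRUE, 10L,
    "ester_like", 102L, 14L, 14L, 1.0, 0.45, 0.75, 0.12,
    list(tibble::tibble(mz = c(74, 59, 43, 41), weight = c(0.60, 0.30, 0.45, 0.15))),
    "Lipids and lipid-like molecules", "Fatty acyls", FALSE, 10L
  )
}

#' Synthetic-data generator configuration
#'
#' Defaults define the study conditions the rest of the package assumes:
#' 1000 compounds drawn evenly from the four [default_scaffolds()],
#' substituent counts uniform on 0--8, a Kovats-like retention-index model
#' `RI = 7 * mass + 100 * aromatic + N(0, 15)`, linear structure-property
#' models with Gaussian noise (log10 molecular weight is exact by
#' definition), and multiplicative log-normal intensity noise with a
#' coefficient of variation of 0.15.
#'
#' @param n_compounds Number of compounds to generate.
#' @param scaffold_mix Named probabilities over scaffold names; must sum to 1.
#' @param substituent_counts Integer support of the substituent-count
#'   distribution (sampled uniformly).
#' @param ri_model List with `intercept`, `mass_slope` (index units per u),
#'   `aromatic_offset`, `noise_sd`.
#' @param property_models Named list, one entry per property except
#'   `log_mw`, each `c(intercept, mass, substituents, aromatic, noise_sd)`.
#' @param intensity_noise_cv Coefficient of variation of the multiplicative
#'   log-normal intensity noise.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param scaffolds Scaffold table, see [default_scaffolds()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 1000,
                             scaffold_mix = c(pcb_like = 0.25,
                                              alkane_like = 0.25,
                                              alkylbenzene = 0.25,
                                              ester_like = 0.25),
                             substituent_counts = 0:8,
                             ri_model = list(intercept = 0,
                                             mass_slope = 7,
                                             aromatic_offset = 100,
                                             noise_sd = 15),
                             property_models = default_property_models(),
                             intensity_noise_cv = 0.15,
                             seed = 1L,
                             scaffolds = default_scaffolds()) {
  if (length(scaffold_mix) == 0) abort("scaffold_mix must not be empty")
  if (abs(sum(scaffold_mix) - 1) > 1e-8) abort("scaffold_mix must sum to 1")
  if (!all(names(scaffold_mix) %in% scaffolds$name)) {
    abort("scaffold_mix names must match scaffold table")
  }
  sds <- c(ri_model$noise_sd, vapply(property_models, function(m) m[["noise_sd"]], 1))
  if (any(sds < 0)) abort("noise sds must be non-negative")
  structure(list(n_compounds = n_compounds, scaffold_mix = scaffold_mix,
                 substituent_counts = substituent_counts, ri_model = ri_model,
                 property_models = property_models,
                 intensity_noise_cv = intensity_noise_cv,
                 seed = as.integer(seed), scaffolds = scaffolds),
            class = "generator_config")
}

#' Default linear structure-property models
#'
#' Coefficients act on (nominal mass in u, substituent count, aromatic
#' 0/1); noise is additive Gaussian. Signs follow the usual physical
#' trends: boiling and melting points and log Kow rise with mass, water
#' solubility and log LD50 fall with it (toxic potency increases). The
#' substituent-count coefficients encode the structural contribution of
#' each added group beyond its mass; because the same nominal mass can
#' arise from different scaffold/substituent combinations, this part of
#' the signal is readable from the full fragmentation pattern but not from
#' any linear function of the summary indicators.
#' @return Named list of coefficient vectors.
#' @export
default_property_models <- function() {
  list(
    bp = c(intercept = 30, mass = 0.9, substituents = 6, aromatic = 20, noise_sd = 8),
    mp = c(intercept = -80, mass = 0.75, substituents = 14, aromatic = 40, noise_sd = 18),
    log_kow = c(intercept = 0.5, mass = 0.011, substituents = 0.2, aromatic = 0.5, noise_sd = 0.3),
    log_ws = c(intercept = 4.5, mass = -0.013, substituents = -0.25, aromatic = -0.8, noise_sd = 0.35),
    log_ld50_rat_oral = c(intercept = 3.6, mass = -0.0035, substituents = -0.18, aromatic = -0.25, noise_sd = 0.3),
    log_ld50_mouse_oral = c(intercept = 3.4, mass = -0.003, substituents = -0.18, aromatic = -0.2, noise_sd = 0.3)
  )
}

#' Simulate an EI spectrum for a substituted scaffold
#'
#' The peak list contains the molecular ion at
#' `base_mass + k * substituent_mass`, one peak per sequential substituent
#' neutral loss (intensity decaying geometrically), and the scaffold's
#' characteristic fragments. All intensities receive multiplicative
#' log-normal noise with the requested coefficient of variation, and the
#' base peak is scaled to 999. Uses the current RNG state; seed upstream.
#'
#' @param scaffold One row of a scaffold table.
#' @param substituent_count Number of substituents (>= 0).
#' @param intensity_noise_cv Noise coefficient of variation.
#' @return Tibble `(mz, intensity)` sorted by m/z.
#' @export
spectrum_from_structure <- function(scaffold, substituent_count,
                                    intensity_noise_cv = 0.15) {
  stopifnot(substituent_count >= 0)
  k <- substituent_count
  mol_ion <- scaffold$base_mass + k * scaffold$substituent_mass
  mz <- mol_ion
  w <- scaffold$mol_ion_weight
  if (k > 0) {
    loss_mz <- mol_ion - seq_len(k) * scaffold$loss_mass
    keep <- loss_mz >= 35
    mz <- c(mz, loss_mz[keep])
    w <- c(w, scaffold$loss_weight * scaffold$loss_decay^(seq_len(k)[keep] - 1))
  }
  frag <- scaffold$fragments[[1]]
  if (!is.data.frame(frag)) frag <- frag[[1]]
  mz <- c(mz, frag$mz)
  # branching ratios drift along the homolog series: characteristic
  # fragments weaken relative to the molecular ion as k grows
  w <- c(w, frag$weight / (1 + scaffold$frag_k_decay * k))
  minor <- minor_fragments(scaffold$base_mass, k, mol_ion)
  mz <- c(mz, minor$mz)
  w <- c(w, minor$weight)
  sdlog <- sqrt(log(1 + intensity_noise_cv^2))
  intensity <- w * exp(rnorm(length(w), mean = 0, sd = sdlog))
  agg <- rowsum(intensity, group = mz)
  out <- tibble::tibble(mz = as.numeric(rownames(agg)),
                        intensity = as.numeric(agg[, 1]))
  out <- out[order(out$mz), ]
  out$intensity <- out$intensity / max(out$intensity) * 999
  out
}

# Compound-specific minor fragments. Real EI spectra carry many weak
# rearrangement/secondary-fragment peaks whose positions are a fixed,
# irregular property of the molecule, not of the measurement; they are
# derived here from a deterministic linear-congruential sequence keyed on
# (scaffold base mass, substituent count), so replicate spectra of one
# compound share them while the occupied-bin count varies irregularly
# between molecules.
minor_fragments <- function(base_mass, k, mol_ion) {
  x <- (7919 * base_mass + 104729 * k + 1) %% 2147483648
  # multiplier kept small enough that the product stays exact in doubles
  step <- function(x) (69069 * x + 12345) %% 2147483648
  x <- step(x)
  n_minor <- 3 + (x %% 5)
  span <- mol_ion - 46
  if (span < 2) return(list(mz = numeric(0), weight = numeric(0)))
  mz <- numeric(n_minor)
  wt <- numeric(n_minor)
  for (j in seq_len(n_minor)) {
    x <- step(x)
    mz[j] <- 40 + (x %% span)
    x <- step(x)
    wt[j] <- 0.02 + (x %% 9) / 100
  }
  keep <- !duplicated(mz)
  list(mz = mz[keep], weight = wt[keep])
}

#' Property values from a structure under the generator's linear models
#'
#' `log_mw` is `log10(nominal mass)` exactly (no noise); every other
#' property is `intercept + b_m * mass + b_k * substituents +
#' b_a * aromatic + N(0, sd)`. Uses the current RNG state.
#'
#' @param nominal_mass Molecular nominal mass in u.
#' @param substituent_count Substituent count.
#' @param aromatic Logical aromatic flag.
#' @param property_models See [default_property_models()].
#' @return Named numeric vector over [property_names()].
#' @export
property_from_structure <- function(nominal_mass, substituent_count, aromatic,
                                    property_models = default_property_models()) {
  needed <- setdiff(PROPERTY_NAMES, "log_mw")
  if (!all(needed %in% names(property_models))) {
    abort("property_models must define every property except log_mw")
  }
  out <- c(log_mw = log10(nominal_mass))
  for (pn in needed) {
    m <- property_models[[pn]]
    mu <- m[["intercept"]] + m[["mass"]] * nominal_mass +
      m[["substituents"]] * substituent_count + m[["aromatic"]] * as.numeric(aromatic)
    out[[pn]] <- mu + rnorm(1, 0, m[["noise_sd"]])
  }
  out
}

#' Generate a synthetic GC-EI-MS dataset
#'
#' Draws scaffolds and substituent counts, simulates spectra, retention
#' indices, taxonomy labels and property values. Deterministic given
#' `config$seed`; the global RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A [spectra_dataset()].
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  n <- config$n_compounds
  sc_tbl <- config$scaffolds
  sc_names <- sample(names(config$scaffold_mix), n, replace = TRUE,
                     prob = config$scaffold_mix)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- sc_tbl[sc_tbl$name == sc_names[i], ]
    supp <- config$substituent_counts
    k <- supp[sample.int(length(supp), 1)]
    k <- min(k, sc$max_substituents)
    peaks <- spectrum_from_structure(sc, k, config$intensity_noise_cv)
    mass <- sc$base_mass + k * sc$substituent_mass
    rim <- config$ri_model
    ri <- rim$intercept + rim$mass_slope * mass +
      rim$aromatic_offset * as.numeric(sc$aromatic) + rnorm(1, 0, rim$noise_sd)
    props <- property_from_structure(mass, k, sc$aromatic,
                                     config$property_models)
    rows[[i]] <- tibble::tibble(
      compound_id = sprintf("SYN%05d", i),
      name = paste0(sc$name, "_k", k, "_", i),
      smiles = scaffold_smiles(sc$name, k),
      ri = ri,
      column_polarity = "semi_polar",
      peaks = list(peaks),
      kingdom = "Organic compounds",
      superclass = sc$superclass,
      class = sc$class,
      scaffold = sc$name,
      substituent_count = k,
      nominal_mass = mass
    )
    rows[[i]][names(props)] <- as.list(props)
  }
  spectra_dataset(dplyr::bind_rows(rows), provenance = "synthetic generator")
}

#' SMILES for a scaffold at a given substituent count
#'
#' Templates are closed so cheminformatics parsing always succeeds:
#' chlorinated biphenyls for `pcb_like` (Cl filled ring-by-ring in a fixed
#' order), unbranched chains for `alkane_like`, n-alkylbenzenes for
#' `alkylbenzene`, and methyl esters with a growing acyl chain for
#' `ester_like`.
#'
#' @param scaffold_name One of the [default_scaffolds()] names.
#' @param substituent_count Substituent count (0 to the scaffold maximum).
#' @return A SMILES string.
#' @export
scaffold_smiles <- function(scaffold_name, substituent_count) {
  k <- substituent_count
  switch(scaffold_name,
    pcb_like = {
      stopifnot(k <= 10)
      mL <- min(k, 5L); mR <- k - mL
      ring_l <- paste0(if (mL >= 1) "c1(Cl)" else "c1",
                       paste0(ifelse(seq_len(4) <= (mL - 1), "c(Cl)", "c"),
                              collapse = ""), "c1")
      ring_r <- paste0("c1",
                       paste0(ifelse(seq_len(4) <= min(mR, 4), "c(Cl)", "c"),
                              collapse = ""), "c1", if (mR >= 5) "Cl" else "")
      paste0(ring_l, "-", ring_r)
    },
    alkane_like = strrep("C", 8 + k),
    alkylbenzene = paste0(strrep("C", 1 + k), "c1ccccc1"),
    ester_like = paste0(strrep("C", 3 + k), "C(=O)OC"),
    abort(paste0("unknown scaffold: ", scaffold_name))
  )
}

#' Generate a homologous-series ladder
#'
#' Replicated spectra of one scaffold across consecutive substituent
#' counts, e.g. a PCB-like chlorination ladder. Used to contrast how
#' spectral and structural similarity behave across a homolog series:
#' fingerprints of adjacent homologs stay close while their mass-shifted
#' spectra diverge.
#'
#' @param scaffold_name Scaffold to ladder.
#' @param substituent_counts Integer vector of consecutive counts.
#' @param replicates Independent noise replicates per count.
#' @param intensity_noise_cv Intensity noise level.
#' @param seed Integer seed.
#' @param config Base configuration supplying scaffold table and models.
#' @return A [spectra_dataset()] with `scaffold`, `substituent_count` and
#'   `replicate` columns.
#' @export
generate_homolog_ladder <- function(scaffold_name = "pcb_like",
                                    substituent_counts = 1:10,
                                    replicates = 5,
                                    intensity_noise_cv = 0.05,
                                    seed = 1L,
                                    config = generator_config(seed = seed)) {
  sc <- config$scaffolds[config$scaffolds$name == scaffold_name, ]
  if (nrow(sc) != 1) abort(paste0("unknown scaffold: ", scaffold_name))
  withr::with_seed(as.integer(seed), {
    rows <- list()
    idx <- 0L
    for (k in substituent_counts) {
      for (r in seq_len(replicates)) {
        idx <- idx + 1L
        peaks <- spectrum_from_structure(sc, k, intensity_noise_cv)
        mass <- sc$base_mass + k * sc$substituent_mass
        rim <- config$ri_model
        ri <- rim$intercept + rim$mass_slope * mass +
          rim$aromatic_offset * as.numeric(sc$aromatic) +
          rnorm(1, 0, rim$noise_sd)
        props <- property_from_structure(mass, k, sc$aromatic,
                                         config$property_models)
        row <- tibble::tibble(
          compound_id = sprintf("HOM%04d", idx),
          name = paste0(scaffold_name, "_k", k, "_r", r),
          smiles = scaffold_smiles(scaffold_name, k),
          ri = ri, column_polarity = "semi_polar", peaks = list(peaks),
          kingdom = "Organic compounds", superclass = sc$superclass,
          class = sc$class, scaffold = scaffold_name,
          substituent_count = k, replicate = r, nominal_mass = mass
        )
        row[names(props)] <- as.list(props)
        rows[[idx]] <- row
      }
    }
    spectra_dataset(dplyr::bind_rows(rows),
                    provenance = "synthetic homolog ladder")
  })
}
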
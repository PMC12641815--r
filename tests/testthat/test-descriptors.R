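test_that("bin_spectrum places peaks on the unit-mass grid", {
  v <- bin_spectrum(tibble::tibble(mz = 100, intensity = 999), 35, 500)
  expect_length(v, 466)
  expect_equal(which(v > 0), 66, ignore_attr = TRUE)  # 100 - 35 + 1
  # round-half-up: 77.2 and 76.8 both land in bin 77 and are summed
  v2 <- bin_spectrum(tibble::tibble(mz = c(76.8, 77.2),
                                    intensity = c(300, 500)),
                     35, 500, base_peak_normalize = FALSE)
  expect_equal(unname(v2[["mz_77"]]), 800)
  expect_error(
    bin_spectrum(tibble::tibble(mz = 34, intensity = 10), 35, 500,
                 compound_id = "badpeak"),
    "badpeak.*outside bin range")
})

test_that("binning conserves total intensity without base-peak scaling", {
  d <- small_dataset(n = 20, seed = 5)
  for (i in 1:5) {
    v <- bin_spectrum(d$peaks[[i]], 35, 600, base_peak_normalize = FALSE)
    expect_equal(sum(v), sum(d$peaks[[i]]$intensity))
  }
})

test_that("standardization gives zero-mean unit-sd columns and is idempotent", {
  d <- small_dataset(n = 40, seed = 6)
  dm <- build_analytical_matrix(d, standardize = TRUE)
  m <- descriptor_features(dm)
  nonconst <- setdiff(colnames(m), attr(dm, "constant_columns"))
  expect_lt(max(abs(colMeans(m[, nonconst]))), 1e-9)
  expect_lt(max(abs(apply(m[, nonconst], 2, sd) - 1)), 1e-9)
  expect_true(all(m[, attr(dm, "constant_columns")] == 0))
  again <- standardize_descriptors(dm)
  expect_lt(max(abs(descriptor_features(again) - m)), 1e-9)
})

test_that("identical spectra standardize to an all-zero matrix", {
  peaks <- tibble::tibble(mz = c(77, 154), intensity = c(300, 999))
  d <- spectra_dataset(tibble::tibble(
    compound_id = c("a", "b"), name = c("a", "b"),
    peaks = list(peaks, peaks), ri = c(1000, 1000)))
  dm <- build_analytical_matrix(d, standardize = TRUE)
  expect_true(all(descriptor_features(dm) == 0))
})

test_that("the without-RI variant drops the RI column and keeps all records", {
  d <- small_dataset(n = 30, seed = 9)
  d$ri[1:5] <- NA
  expect_message(with_ri <- build_analytical_matrix(d), "dropped 5")
  no_ri <- build_analytical_matrix(d, include_ri = FALSE)
  expect_true("ri" %in% attr(with_ri, "feature_names"))
  expect_false("ri" %in% attr(no_ri, "feature_names"))
  expect_equal(nrow(with_ri), 25)
  expect_equal(nrow(no_ri), 30)
  expect_equal(attr(no_ri, "descriptor_kind"), "analytical_no_ri")
})

test_that("molecular and analytical matrices stay row-aligned", {
  d <- small_dataset(n = 15, seed = 10)
  a <- build_analytical_matrix(d)
  m <- build_molecular_matrix(d, "ecfp6")
  expect_equal(a$compound_id, d$compound_id)
  expect_equal(m$compound_id, d$compound_id)
})

test_that("MACCS keys have 166 bits with the aromatic-ring bit set for benzene", {
  d <- spectra_dataset(tibble::tibble(
    compound_id = c("benzene", "hexane"), name = c("benzene", "hexane"),
    smiles = c("c1ccccc1", "CCCCCC"),
    peaks = list(tibble::tibble(mz = 78, intensity = 999),
                 tibble::tibble(mz = 86, intensity = 999))))
  dm <- build_molecular_matrix(d, "maccs")
  m <- descriptor_features(dm)
  expect_equal(ncol(m), 166)
  expect_equal(unname(m["benzene", "maccs_162"]), 1)  # MACCS 162 = aromatic
  expect_equal(unname(m["hexane", "maccs_162"]), 0)
  expect_true(all(m %in% c(0, 1)))
})

test_that("fingerprints are deterministic and unparseable SMILES are dropped", {
  d <- spectra_dataset(tibble::tibble(
    compound_id = c("a", "b", "c"), name = c("a", "b", "c"),
    smiles = c("CCO", "CCO", "not(a)smiles(((Q"),
    peaks = replicate(3, tibble::tibble(mz = 46, intensity = 999),
                      simplify = FALSE)))
  expect_message(fp <- build_molecular_matrix(d, "ecfp6"), "dropped 1")
  m <- descriptor_features(fp)
  expect_equal(nrow(m), 2)
  expect_equal(m["a", ], m["b", ])
})

test_that("topological descriptors carry mass information and standardize on request", {
  d <- small_dataset(n = 12, seed = 4)
  raw <- build_molecular_matrix(d, "topological")
  expect_true("MW" %in% attr(raw, "feature_names"))
  expect_gt(cor(descriptor_features(raw)[, "MW"], d$nominal_mass), 0.99)
  std <- build_molecular_matrix(d, "topological", standardize_continuous = TRUE)
  expect_true(attr(std, "standardized"))
})

test_that("the 881-bit substructure key flags rings, chlorine and esters", {
  bits_pcb <- pubchem_key_bits("c1(Cl)ccccc1-c1ccccc1")
  bits_ester <- pubchem_key_bits("CCCC(=O)OC")
  expect_length(bits_pcb, 881)
  expect_true(all(c(bits_pcb, bits_ester) %in% c(0, 1)))
  smarts_bit <- function(bits, name) {
    bits[263 + which(names(PUBCHEM_SMARTS) == name)]
  }
  expect_equal(smarts_bit(bits_pcb, "benzene"), 1)
  expect_equal(smarts_bit(bits_pcb, "halide_on_c"), 1)
  expect_equal(smarts_bit(bits_ester, "ester"), 1)
  expect_equal(smarts_bit(bits_ester, "benzene"), 0)
  d <- small_dataset(n = 4, seed = 13)
  pc <- build_molecular_matrix(d, "pubchem")
  expect_equal(attr(pc, "provenance"), "synthetic-substructure-key")
})

test_that("tanimoto similarity behaves on bit vectors", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(tanimoto(c(1, 0), c(1, 0)), 1)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)
})
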
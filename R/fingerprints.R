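# Molecular descriptors: circular (Morgan) fingerprints hashed in-package,
# MACCS structure keys from Open Babel, an in-package 881-bit
# PubChem-layout substructure key (synthetic key: a documented subset of
# positions is populated, see pubchem_key_bits()), and continuous
# topological/constitutional descriptors.

#' Build a molecular descriptor matrix
#'
#' Computes one of four structure-derived descriptor sets from the SMILES
#' column of a dataset. Records whose SMILES cannot be parsed are dropped
#' with a message; surviving rows keep the dataset's order so analytical
#' and molecular matrices built from the same dataset are index-aligned.
#'
#' * `ecfp6`: circular Morgan fingerprint, radius 3, hashed to
#'   `n_bits` bits (in-package implementation, see [morgan_fingerprint()]).
#' * `maccs`: the 166-bit MACCS structure key (Open Babel).
#' * `pubchem`: an 881-bit substructure key laid out like the PubChem
#'   fingerprint; a documented subset of positions is populated from
#'   element counts, ring features and SMARTS patterns (the matrix carries
#'   `provenance = "synthetic-substructure-key"`).
#' * `topological`: continuous constitutional/topological descriptors
#'   (molecular weight, logP, molar refractivity, TPSA, H-bond counts,
#'   atom/bond/ring counts, Wiener index, ...); standardized when
#'   `standardize_continuous = TRUE`, mirroring the treatment of
#'   continuous variables ahead of embedding.
#'
#' @param data A [spectra_dataset()] with SMILES.
#' @param kind One of `"ecfp6"`, `"maccs"`, `"pubchem"`, `"topological"`.
#' @param standardize_continuous Z-score the topological descriptors.
#' @param n_bits Hashed length of the circular fingerprint.
#' @return A `descriptor_matrix` tibble.
#' @export
build_molecular_matrix <- function(data, kind = c("ecfp6", "maccs", "pubchem",
                                                  "topological"),
                                   standardize_continuous = FALSE,
                                   n_bits = 1024L) {
  kind <- rlang::arg_match(kind)
  smiles <- data$smiles
  parseable <- !is.na(smiles) & vapply(smiles, smiles_ok, logical(1))
  if (any(!parseable)) {
    inform(paste0("dropped ", sum(!parseable),
                  " records with missing or unparseable SMILES"))
  }
  if (!any(parseable)) abort("no parseable SMILES in dataset")
  d <- data[parseable, ]
  m <- switch(kind,
    ecfp6 = {
      graphs <- parse_molecules(d$smiles)
      t(vapply(graphs, morgan_fingerprint, numeric(n_bits),
               radius = 3L, n_bits = n_bits))
    },
    maccs = {
      fp <- with_ob_mols(d$smiles, function(mols)
        ChemmineOB::fingerprint_OB(mols, "MACCS"))
      fp <- matrix(fp, nrow = nrow(d))[, 1:166, drop = FALSE]
      colnames(fp) <- paste0("maccs_", 1:166)
      fp
    },
    pubchem = t(vapply(d$smiles, pubchem_key_bits, numeric(881L))),
    topological = {
      graphs <- parse_molecules(d$smiles)
      props <- with_ob_mols(d$smiles, ChemmineOB::prop_OB)
      topo <- t(vapply(graphs, graph_descriptors, numeric(8)))
      cbind(as.matrix(props[, c("MW", "logP", "MR", "TPSA",
                                "HBA1", "HBA2", "HBD", "nF")]), topo)
    }
  )
  if (kind %in% c("ecfp6", "pubchem")) {
    colnames(m) <- paste0(if (kind == "ecfp6") "fp_" else "pc_",
                          seq_len(ncol(m)))
  }
  dm <- new_descriptor_matrix(
    m, d$compound_id, kind = kind,
    extra_attrs = if (kind == "pubchem")
      list(provenance = "synthetic-substructure-key") else list())
  if (kind == "topological" && standardize_continuous) {
    standardize_descriptors(dm)
  } else {
    dm
  }
}

smiles_ok <- function(smi) {
  !inherits(tryCatch(ChemmineOB::forEachMol("SMILES", smi, identity),
                     error = function(e) e), "error")
}

with_ob_mols <- function(smiles, f) {
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  f(mols)
}

# --- molecular graphs ------------------------------------------------------

# Parse SMILES into light molecular graphs (atom elements, bond list with
# orders, implicit hydrogen estimates, ring membership) by converting to SDF
# with Open Babel and reading the blocks with ChemmineR.
parse_molecules <- function(smiles) {
  sdfstr <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(paste(smiles, seq_along(smiles)), collapse = "\n"))
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(sdfstr, tmp)
  sdfset <- ChemmineR::read.SDFset(tmp)
  if (length(sdfset) != length(smiles)) {
    abort("SMILES to SDF conversion lost molecules")
  }
  lapply(seq_along(smiles), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- if (nrow(bb) > 0) {
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else {
      data.frame(a1 = integer(), a2 = integer(), order = integer())
    }
    graph_from_blocks(elements, bonds)
  })
}

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, B = 3, Si = 4)

graph_from_blocks <- function(elements, bonds) {
  n <- length(elements)
  degree <- integer(n)
  valence <- integer(n)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[b]; a2 <- bonds$a2[b]; o <- bonds$order[b]
    degree[a1] <- degree[a1] + 1L
    degree[a2] <- degree[a2] + 1L
    valence[a1] <- valence[a1] + o
    valence[a2] <- valence[a2] + o
    adj[[a1]] <- c(adj[[a1]], b)
    adj[[a2]] <- c(adj[[a2]], b)
  }
  nh <- pmax(0L, unname(STANDARD_VALENCE[elements]) - valence)
  nh[is.na(nh)] <- 0L
  list(elements = elements, bonds = bonds, degree = degree,
       valence = valence, n_h = nh, adj = adj,
       ring_bond = ring_bonds(n, bonds))
}

# A bond lies on a ring iff its endpoints stay connected when it is removed.
ring_bonds <- function(n, bonds) {
  nb <- nrow(bonds)
  out <- logical(nb)
  if (nb == 0) return(out)
  for (b in seq_len(nb)) {
    seen <- logical(n)
    queue <- bonds$a1[b]
    seen[queue] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (bb in seq_len(nb)) {
        if (bb == b) next
        w <- if (bonds$a1[bb] == v) bonds$a2[bb]
             else if (bonds$a2[bb] == v) bonds$a1[bb] else next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    out[b] <- seen[bonds$a2[b]]
  }
  out
}

# --- circular fingerprint --------------------------------------------------

# Deterministic 31-bit polynomial hash of an integer vector.
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Circular (Morgan) fingerprint of a molecular graph
#'
#' ECFP-style iterative neighborhood hashing: initial atom identifiers are
#' hashes of (element, heavy-atom degree, implicit hydrogen count, total
#' bond order, ring membership); each round folds in the sorted
#' (bond order, neighbor identifier) pairs. All identifiers produced up to
#' the requested radius are folded onto `n_bits` positions. Radius 3
#' (diameter 6) corresponds to the common "ECFP6" setting. Hash values are
#' package-specific; bit patterns are comparable within this package, not
#' with other toolkits.
#'
#' @param graph A molecular graph from the internal parser.
#' @param radius Neighborhood radius (default 3).
#' @param n_bits Folded length.
#' @return 0/1 numeric vector of length `n_bits`.
#' @export
morgan_fingerprint <- function(graph, radius = 3L, n_bits = 1024L) {
  n <- length(graph$elements)
  elem_code <- match(graph$elements, names(STANDARD_VALENCE))
  elem_code[is.na(elem_code)] <- 99L
  atom_ring <- vapply(seq_len(n), function(a)
    any(graph$ring_bond[graph$adj[[a]]]), logical(1))
  ids <- vapply(seq_len(n), function(a) {
    hash_ints(c(elem_code[a], graph$degree[a], graph$n_h[a],
                graph$valence[a], as.integer(atom_ring[a])))
  }, numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(a) {
      nb <- lapply(graph$adj[[a]], function(b) {
        other <- if (graph$bonds$a1[b] == a) graph$bonds$a2[b]
                 else graph$bonds$a1[b]
        c(graph$bonds$order[b], ids[other])
      })
      if (length(nb) > 0) {
        ord <- order(vapply(nb, `[`, numeric(1), 1),
                     vapply(nb, `[`, numeric(1), 2))
        nb <- unlist(nb[ord])
      } else {
        nb <- numeric(0)
      }
      hash_ints(c(r, ids[a], nb))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  fp <- numeric(n_bits)
  fp[(all_ids %% n_bits) + 1] <- 1
  fp
}

# --- PubChem-layout substructure key --------------------------------------

PUBCHEM_SMARTS <- c(
  benzene = "c1ccccc1", arom_n = "n", arom_cl = "cCl", arom_c_alkyl = "cC",
  biaryl = "c-c", carbonyl = "[#6]=[#8]", ester = "C(=O)OC",
  carboxyl = "C(=O)[OX2H1]", hydroxyl = "[OX2H]", ether = "[OX2]([#6])[#6]",
  amine = "[NX3]", thio = "[#16]", alkene = "C=C", alkyne = "C#C",
  chain4 = "CCCC", chain6 = "CCCCCC", isopropyl = "CC(C)C",
  methyl = "[CH3]", halide_on_c = "[#6][F,Cl,Br,I]", nitro = "[N+](=O)[O-]",
  nitrile = "C#N", amide = "C(=O)N", ring5 = "[r5]", ring6 = "[r6]"
)

#' PubChem-layout 881-bit substructure key (synthetic key)
#'
#' A structure key the length and broad layout of the PubChem fingerprint,
#' populated from quantities this package can compute: bits 1--48 encode
#' element-count thresholds (C, N, O, S, Cl, F, Br, P, and implicit H),
#' bits 115--120 ring-count and aromatic-ring thresholds, and bits
#' 264--263+k presence of the `k` SMARTS patterns in `PUBCHEM_SMARTS`
#' (matched with Open Babel). All other positions are zero. This is a
#' package-defined key, not the PubChem reference implementation.
#'
#' @param smiles A single SMILES string.
#' @return 0/1 numeric vector of length 881.
#' @export
pubchem_key_bits <- function(smiles) {
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  graphs <- parse_molecules(smiles)
  g <- graphs[[1]]
  counts <- table(g$elements)
  cnt <- function(e) if (e %in% names(counts)) counts[[e]] else 0L
  n_h <- sum(g$n_h)
  bits <- numeric(881)
  thresholds <- list(C = c(2, 4, 8, 16, 24, 32), N = c(1, 2, 4),
                     O = c(1, 2, 4, 8), S = c(1, 2), Cl = c(1, 2, 4, 8),
                     F = c(1, 2), Br = 1, P = 1, H = c(4, 8, 16, 24, 32))
  pos <- 1L
  for (e in names(thresholds)) {
    value <- if (e == "H") n_h else cnt(e)
    for (th in thresholds[[e]]) {
      bits[pos] <- as.numeric(value >= th)
      pos <- pos + 1L
    }
  }
  n_ring_bonds <- sum(g$ring_bond)
  n_rings <- nrow(g$bonds) - length(g$elements) + 1L  # cyclomatic, connected
  n_arom_rings <- ChemmineOB::smartsSearch_OB(mol, "c1ccccc1") +
    ChemmineOB::smartsSearch_OB(mol, "c1ccncc1")
  bits[115] <- as.numeric(n_rings >= 1)
  bits[116] <- as.numeric(n_rings >= 2)
  bits[117] <- as.numeric(n_arom_rings >= 1)
  bits[118] <- as.numeric(n_arom_rings >= 2)
  bits[119] <- as.numeric(n_ring_bonds >= 5)
  bits[120] <- as.numeric(n_ring_bonds >= 10)
  for (j in seq_along(PUBCHEM_SMARTS)) {
    hit <- tryCatch(
      ChemmineOB::smartsSearch_OB(mol, PUBCHEM_SMARTS[[j]]) > 0,
      error = function(e) FALSE)
    bits[263 + j] <- as.numeric(hit)
  }
  bits
}

# --- continuous graph descriptors -----------------------------------------

graph_descriptors <- function(g) {
  n <- length(g$elements)
  n_rings <- nrow(g$bonds) - n + 1L
  hetero <- sum(!g$elements %in% c("C", "H"))
  halogens <- sum(g$elements %in% c("F", "Cl", "Br", "I"))
  branch <- sum(g$degree >= 3)
  c(n_atoms = n, n_bonds = nrow(g$bonds), n_rings = max(0L, n_rings),
    n_ring_atoms = sum(vapply(seq_len(n), function(a)
      any(g$ring_bond[g$adj[[a]]]), logical(1))),
    n_hetero = hetero, n_halogen = halogens, n_branch = branch,
    wiener = wiener_index(g))
}

# Wiener index: sum of shortest-path lengths over unordered heavy-atom pairs.
wiener_index <- function(g) {
  n <- length(g$elements)
  if (n < 2) return(0)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (b in seq_len(nrow(g$bonds))) {
    d[g$bonds$a1[b], g$bonds$a2[b]] <- 1
    d[g$bonds$a2[b], g$bonds$a1[b]] <- 1
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  sum(d[upper.tri(d)])
}

#' Tanimoto similarity of two bit vectors
#'
#' @param u,v 0/1 vectors of equal length.
#' @return `|u & v| / |u | v|`; 0 when both vectors are empty.
#' @export
tanimoto <- function(u, v) {
  stopifnot(length(u) == length(v))
  int <- sum(u > 0 & v > 0)
  un <- sum(u > 0 | v > 0)
  if (un == 0) return(0)
  int / un
}
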
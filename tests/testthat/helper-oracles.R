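# Independent oracles and shared fixtures for the test suite.

# Floyd-Warshall all-pairs shortest paths from the bond list alone
# (independent of the BFS distances stored on the molgraph).
fw_distances <- function(n_atoms, bonds) {
  D <- matrix(Inf, n_atoms, n_atoms)
  diag(D) <- 0
  for (r in seq_len(nrow(bonds))) {
    D[bonds$i[r], bonds$j[r]] <- 1
    D[bonds$j[r], bonds$i[r]] <- 1
  }
  for (k in seq_len(n_atoms)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Brute-force proximity descriptor: explicit loops over atom pairs using
# the Floyd-Warshall matrix, mirroring the descriptor definitions.
brute_proximity <- function(mol, spec) {
  D <- fw_distances(nrow(mol$atoms), mol$bonds)
  A <- classify_atoms(mol, spec$source_class)
  B <- classify_atoms(mol, spec$target_class)
  if (length(A) == 0 || length(B) == 0) return(0L)
  if (spec$mode == "pairs_le_k") {
    cnt <- 0L
    for (a in A) for (b in B) {
      if (D[a, b] >= 1 && D[a, b] <= spec$k) cnt <- cnt + 1L
    }
    return(cnt)
  }
  cnt <- 0L
  for (b in B) {
    dmin <- Inf
    for (a in setdiff(A, b)) dmin <- min(dmin, D[a, b])
    hit <- if (spec$mode == "exactly_k_excl") dmin == spec$k else
      (dmin >= 1 && dmin <= spec$k)
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

# A small library of real drug-like SMILES to exercise ring systems,
# heteroatoms and charges.
DRUGLIKE_SMILES <- c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  pyridine = "c1ccncc1",
  imidazole = "c1cnc[nH]1",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  benzamidine = "NC(=N)c1ccccc1",
  chlorobenzene = "Clc1ccccc1",
  diazepamish = "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",
  ether_ester = "COCCOC(C)=O",
  guanidine = "NC(=N)NCCc1ccncc1",
  table1_mol1 = "COc1cc(Cl)cc(C(=O)Nc2ccc(Cl)cn2)c1NC(=O)c1scc(CN(C)C2=NCCO2)c1Cl",
  disconnected = "CCOC(C)=O.NCCCl"
)

# Random motif-bearing synthetic molecules (SMILES), seed-reproducible.
random_molecules <- function(n, seed = 1) {
  plans <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      rec <- list()
      if (runif(1) < 0.5) rec <- c(rec, list(motif_recipe("Cl_amideN_at_k",
        k = sample(2:9, 1L), count = sample(1:2, 1L))))
      if (runif(1) < 0.5) rec <- c(rec, list(motif_recipe("sp2O_sp3O_at_k",
        k = sample(2:9, 1L))))
      if (runif(1) < 0.5) rec <- c(rec, list(motif_recipe("aroN_ring",
        count = sample(1:2, 1L))))
      list(rec = rec, seed = sample.int(1e6, 1L))
    })
  })
  vapply(plans, function(p) gen_motif_molecule(p$rec, seed = p$seed,
                                               check = FALSE), character(1))
}

# Mixed pool used by engine-vs-oracle and invariant tests.
test_molecule_pool <- function(n_random = 30, seed = 1) {
  smiles <- c(DRUGLIKE_SMILES, random_molecules(n_random, seed))
  parse_molecules(unname(smiles), ids = paste0("tm", seq_along(smiles)))
}

# SMILES of Table 1 (the ten most/least active molecules of the study),
# used as real-world parse and prediction inputs.
TABLE1_SMILES <- c(
  "COc1cc(Cl)cc(C(=O)Nc2ccc(Cl)cn2)c1NC(=O)c1scc(CN(C)C2=NCCO2)c1Cl",
  "COc1cc(Cl)cc(C(=O)Nc2ccc(Cl)cn2)c1NC(=O)c1scc(CN(C)C2=NCCCO2)c1Cl",
  "CCN(Cc1csc(C(=O)Nc2c(OC)cc(Cl)cc2C(=O)Nc2ccc(Cl)cn2)c1Cl)C1=NCCO1",
  "COc1cc(Cl)cc(C(=O)Nc2ccc(Cl)cn2)c1NC(=O)c1ccc(-n2ccccc2=O)cc1",
  "COc1cc(Cl)cc(C(=O)Nc2ccc(Cl)cn2)c1NC(=O)c1scc(CN(C)C2=NCCS2)c1Cl",
  "C=Cc1cc(OC2CCOCC2)cc(C(Nc2ccc(C(=N)N)cc2)C(=O)O)c1",
  "C#Cc1cc(O[C@@H]2CCOC2)cc(C(Nc2ccc(C(=N)N)cc2)C(=O)O)c1",
  "CC(C)(C)OC(=O)[C@@H](Cc1ccc(O)cc1)NC(=O)c1cccc(C(=N)N)c1",
  "CN1CC(C)(COc2ccc(C(=N)N)cc2)Oc2cc(N(Cc3ccccc3)C(=O)C(=O)O)ccc21",
  "CCOC(=O)CCC(=O)N(Cc1ccccc1)c1ccc2c(c1)OC(C)(COc1ccc(C(=N)N)cc1)CN2C"
)
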
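test_that("benzene parses with full aromatic perception", {
  m <- parse_molecule("c1ccccc1")
  expect_equal(nrow(m$atoms), 6)
  expect_true(all(m$atoms$aromatic))
  expect_true(all(m$atoms$in_ring))
  expect_true(all(m$atoms$hybridization == "sp2"))
  expect_true(all(m$dist[upper.tri(m$dist)] <= 3))
})

test_that("acetamide atoms are classified as amide N and sp2 O", {
  m <- parse_molecule("CC(N)=O")
  expect_length(classify_atoms(m, "amideN"), 1)
  expect_length(classify_atoms(m, "sp2O"), 1)
  expect_length(classify_atoms(m, "sp3O"), 0)
})

test_that("a multi-ring chlorinated inhibitor parses with expected atom content", {
  m <- parse_molecule(DRUGLIKE_SMILES[["table1_mol1"]])
  expect_gte(length(classify_atoms(m, "aroN")), 1)
  expect_gte(length(classify_atoms(m, "Cl")), 3)
  expect_gte(length(classify_atoms(m, "amideN")), 2)
})

test_that("unparseable SMILES raises an error naming the molecule id", {
  expect_error(parse_molecules(c("CCO", "C1CC"), ids = c("ok", "broken")),
               "broken")
})

test_that("classification handles empty and singleton classes", {
  expect_length(classify_atoms(parse_molecule("c1ccccc1"), "aroN"), 0)
  expect_length(classify_atoms(parse_molecule("c1ccncc1"), "aroN"), 1)
  expect_error(classify_atoms(parse_molecule("C"), "noSuchClass"),
               "unknown atom class")
})

test_that("distance matrices agree with a Floyd-Warshall oracle", {
  mols <- test_molecule_pool(n_random = 15, seed = 101)
  for (m in mols) {
    D <- fw_distances(nrow(m$atoms), m$bonds)
    expect_equal(m$dist, D, ignore_attr = TRUE)
  }
})

test_that("distance matrices satisfy metric invariants", {
  mols <- test_molecule_pool(n_random = 10, seed = 202)
  for (m in mols) {
    D <- m$dist
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    bonded <- matrix(FALSE, nrow(D), ncol(D))
    for (r in seq_len(nrow(m$bonds))) {
      bonded[m$bonds$i[r], m$bonds$j[r]] <- TRUE
      bonded[m$bonds$j[r], m$bonds$i[r]] <- TRUE
    }
    expect_equal(unname(D == 1), bonded)
    # triangle inequality over a sample of triples
    n <- nrow(D)
    if (n >= 3) {
      idx <- utils::combn(seq_len(min(n, 8)), 3)
      for (c_ in seq_len(ncol(idx))) {
        i <- idx[1, c_]; j <- idx[2, c_]; k <- idx[3, c_]
        expect_true(D[i, j] <= D[i, k] + D[k, j])
      }
    }
  }
})

test_that("atom classes nest and exclude as chemistry dictates", {
  mols <- test_molecule_pool(n_random = 15, seed = 303)
  for (m in mols) {
    sp3O <- classify_atoms(m, "sp3O"); sp2O <- classify_atoms(m, "sp2O")
    expect_length(intersect(sp3O, sp2O), 0)
    aroC <- classify_atoms(m, "aroC")
    expect_true(all(classify_atoms(m, "aroCplus") %in% aroC))
    expect_true(all(aroC %in% classify_atoms(m, "sp2C")))
    expect_true(all(classify_atoms(m, "ringCplus") %in%
                      classify_atoms(m, "ringC")))
    expect_true(all(m$atoms$in_ring[classify_atoms(m, "aroC")]))
  }
})

test_that("pKi transform matches hand-computed and reported values", {
  expect_equal(round(to_pki(0.007), 3), 11.155)
  expect_equal(round(to_pki(18000), 3), 4.745)
  expect_equal(to_pki(1.0), 9.000)
  expect_error(to_pki(0), "positive")
  expect_error(to_pki(-3), "positive")
})

test_that("curation drops qualified Ki, metals and duplicates", {
  raw <- data.frame(
    id = c("metal", "dup1", "a", "b", "dup2"),
    smiles = c("Cl[Hg]Cl", "c1ccccc1O", "CCO", "CC(N)=O", "Oc1ccccc1"),
    ki_nM = c("10", "25", "100", "3.5", "25"),
    stringsAsFactors = FALSE
  )
  cur <- curate(raw)
  expect_equal(nrow(cur), 3)
  expect_setequal(cur$id, c("dup1", "a", "b"))
  expect_equal(cur$pki, to_pki(cur$ki_nM))

  qual <- data.frame(id = c("q1", "q2", "q3", "ok"),
                     smiles = c("CCO", "CCN", "CCS", "CCC"),
                     ki_nM = c(">100", "", "n.d.", "50"))
  expect_equal(curate(qual)$id, "ok")
})

test_that("curation strips salts to the largest organic fragment", {
  raw <- data.frame(id = "salt", smiles = "CC(=O)Oc1ccccc1C(=O)O.[Na+]",
                    ki_nM = "12")
  cur <- curate(raw)
  expect_equal(nrow(cur), 1)
  expect_false(grepl("Na", cur$canonical_smiles))
  expect_false(grepl(".", cur$canonical_smiles, fixed = TRUE))
})

test_that("curation is idempotent", {
  raw <- data.frame(
    id = c("a", "b", "c", "d"),
    smiles = c("CCO.CC", "c1ccncc1", "CC(N)=O", "OCC"),
    ki_nM = c("10", "20", "30", "40")
  )
  once <- curate(raw)
  twice <- curate(once)
  expect_equal(twice, once)
})
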
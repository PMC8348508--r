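spec_fClamdN5B <- named_descriptor_set()$fClamdN5B

test_that("amide-N/chlorine proximity counts exact minimum distances", {
  # Cl-C-C-C-C-N: five bonds from the chlorine to the amide nitrogen
  expect_equal(proximity_value(parse_molecule("ClCCCCNC(C)=O"),
                               spec_fClamdN5B), 1)
  # three bonds only: excluded by the exact-distance rule
  expect_equal(proximity_value(parse_molecule("ClCCNC(C)=O"),
                               spec_fClamdN5B), 0)
})

test_that("proximity descriptors are zero for empty atom classes", {
  benzene <- parse_molecule("c1ccccc1")
  for (s in named_descriptor_set()) {
    if (s$kind != "count") {
      expect_equal(descriptor_value(benzene, s), 0)
    }
  }
})

test_that("distances never cross disconnected fragments", {
  m <- parse_molecule(DRUGLIKE_SMILES[["disconnected"]])  # ester . chloramine
  expect_true(any(is.infinite(m$dist)))
  # the sp3 O sits in the ester fragment, the Cl in the other: no count
  spec <- descriptor_spec("x", "proximity", target_class = "sp3O",
                          source_class = "Cl", k = 12, mode = "within_le_k")
  expect_equal(proximity_value(m, spec), 0)
})

test_that("charge sums over ring carbons behave as expected", {
  expect_equal(charge_sum_value(parse_molecule("C"), "ringCplus"), 0)
  expect_equal(charge_sum_value(parse_molecule("C1CCCCC1"), "ringCplus"), 0)
  expect_gt(charge_sum_value(parse_molecule("c1ccncc1"), "ringCplus"), 0)
})

test_that("the named descriptor set enumerates the model and comparator specs", {
  specs <- named_descriptor_set()
  expect_length(specs, 16)
  f_specs <- specs[grepl("^f", names(specs))]
  expect_true(all(vapply(f_specs, function(s) s$mode == "exactly_k_excl",
                         logical(1))))
  expect_equal(specs$aroN_sp2C_4B$k, 4)
  expect_equal(specs$aroN_sp2C_4B$mode, "within_le_k")
  expect_equal(specs$ringCplus_sumpc$kind, "charge_sum")
  expect_setequal(
    vapply(specs, `[[`, character(1), "name")[1:6],
    c("ringCplus_sumpc", "aroN_sp2C_4B", "fClamdN5B", "fsp2Osp3O6B",
      "fsp2Nsp3O9B", "fsp2Csp2O8B"))
})

test_that("exact-distance counts partition the within-k counts", {
  mols <- test_molecule_pool(n_random = 25, seed = 404)
  pairs <- list(c("Cl", "amideN"), c("sp2O", "sp3O"), c("sp2C", "aroN"))
  for (m in mols) {
    for (pr in pairs) {
      for (K in c(3, 6, 12)) {
        exact_sum <- sum(vapply(seq_len(K), function(k) {
          proximity_value(m, descriptor_spec("e", "proximity",
            target_class = pr[2], source_class = pr[1], k = k,
            mode = "exactly_k_excl"))
        }, numeric(1)))
        within <- proximity_value(m, descriptor_spec("w", "proximity",
          target_class = pr[2], source_class = pr[1], k = K,
          mode = "within_le_k"))
        expect_equal(exact_sum, within)
      }
    }
  }
})

test_that("proximity counts are monotone and bounded", {
  mols <- test_molecule_pool(n_random = 15, seed = 505)
  for (m in mols) {
    B <- length(classify_atoms(m, "sp3O"))
    prev <- 0
    for (k in 1:12) {
      w <- proximity_value(m, descriptor_spec("w", "proximity",
        target_class = "sp3O", source_class = "sp2C", k = k,
        mode = "within_le_k"))
      e <- proximity_value(m, descriptor_spec("e", "proximity",
        target_class = "sp3O", source_class = "sp2C", k = k,
        mode = "exactly_k_excl"))
      p <- proximity_value(m, descriptor_spec("p", "proximity",
        target_class = "sp3O", source_class = "sp2C", k = k,
        mode = "pairs_le_k"))
      expect_gte(w, prev)
      expect_lte(e, B)
      expect_gte(p, w)
      prev <- w
    }
  }
})

test_that("the descriptor engine matches a brute-force pair-loop oracle", {
  mols <- test_molecule_pool(n_random = 40, seed = 606)
  specs <- Filter(function(s) s$kind == "proximity", named_descriptor_set())
  extra <- list(
    descriptor_spec("pp", "proximity", target_class = "aroN",
                    source_class = "Cl", k = 7, mode = "pairs_le_k"),
    descriptor_spec("pw", "proximity", target_class = "sp2O",
                    source_class = "sp2O", k = 5, mode = "within_le_k")
  )
  for (m in mols) {
    for (s in c(specs, extra)) {
      expect_equal(proximity_value(m, s), brute_proximity(m, s),
                   info = paste(m$id, s$name))
    }
  }
})

test_that("the descriptor matrix is deterministic and equals the single-spec loop", {
  mols <- test_molecule_pool(n_random = 10, seed = 707)
  specs <- named_descriptor_set()
  X1 <- compute_matrix(mols, specs)
  X2 <- compute_matrix(mols, specs)
  expect_identical(X1, X2)
  for (i in seq_along(mols)) {
    row <- vapply(specs, function(s) as.numeric(descriptor_value(mols[[i]], s)),
                  numeric(1))
    expect_equal(unname(X1[i, ]), unname(row))
  }
  expect_true(all(X1[, colnames(X1) != "ringCplus_sumpc"] >= 0))
  expect_true(all(X1[, colnames(X1) != "ringCplus_sumpc"] ==
                    round(X1[, colnames(X1) != "ringCplus_sumpc"])))
})

test_that("descriptor registries round-trip through JSON", {
  specs <- named_descriptor_set()
  path <- withr::local_tempfile(fileext = ".json")
  write_descriptor_registry(specs, path)
  back <- read_descriptor_registry(path)
  expect_equal(names(back), names(specs))
  for (nm in names(specs)) {
    expect_equal(back[[nm]][c("kind", "target_class", "source_class",
                              "k", "mode")],
                 specs[[nm]][c("kind", "target_class", "source_class",
                               "k", "mode")])
  }
})
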
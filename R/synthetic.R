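#' Motif recipe for synthetic molecule generation
#'
#' Supported motifs mirror the descriptor definitions of the factor Xa
#' model:
#' \describe{
#'   \item{Cl_amideN_at_k}{an amide nitrogen whose nearest chlorine is
#'     exactly `k` bonds away (drives `fClamdN5B`-style descriptors);
#'     `k >= 2`}
#'   \item{sp2O_sp3O_at_k}{an sp3 (ether) oxygen exactly `k` bonds from a
#'     carbonyl (sp2) oxygen; `k >= 2`}
#'   \item{aroN_ring}{a pyridine ring contributing an aromatic nitrogen}
#'   \item{ring_with_positive_C}{an aromatic ring carrying positively
#'     charged ring carbons (pyridine: the carbons alpha to N)}
#' }
#'
#' @param motif one of the motif names above.
#' @param k target bond distance (distance motifs only).
#' @param count number of copies of the motif.
#' @return a `motif_recipe` list.
#' @export
motif_recipe <- function(motif, k = NULL, count = 1L) {
  motif <- match.arg(motif, c("Cl_amideN_at_k", "sp2O_sp3O_at_k",
                              "aroN_ring", "ring_with_positive_C"))
  if (motif %in% c("Cl_amideN_at_k", "sp2O_sp3O_at_k")) {
    stopifnot(!is.null(k), k >= 2L)
  } else k <- NULL
  stopifnot(count >= 1L)
  structure(list(motif = motif, k = k, count = count),
            class = "motif_recipe")
}

# Substituent SMILES realizing each motif when attached to an sp3 backbone
# carbon. Distances are exact by construction.
.motif_substituent <- function(recipe) {
  switch(recipe$motif,
    # backbone-N(H)-C(=O)-(CH2)_{k-2}-Cl : N..Cl = k bonds
    Cl_amideN_at_k = paste0("NC(=O)", strrep("C", recipe$k - 2L), "Cl"),
    # backbone-O-(CH2)_{k-2}-C(C)=O : O(sp3)..O(sp2) = k bonds
    sp2O_sp3O_at_k = paste0("O", strrep("C", recipe$k - 2L), "C(C)=O"),
    aroN_ring = "c1ccncc1",
    ring_with_positive_C = "c1ccncc1"
  )
}

#' Generate a synthetic molecule realizing a set of motifs
#'
#' Molecules are assembled by template: each motif becomes a substituent on
#' a long alkane backbone, attachment points separated by `gap` methylenes
#' so motifs cannot interfere with one another's exact distances (all
#' cross-motif distances exceed the 12-bond descriptor range). The `seed`
#' shuffles substituent order and the length of a terminal alkyl tail.
#'
#' @param recipes list of [motif_recipe()] objects (may be empty: a plain
#'   alkane results).
#' @param seed integer RNG seed.
#' @param gap backbone methylenes between attachment points (default 14).
#' @param check verify by parsing that every requested motif is realized
#'   (default TRUE).
#' @return a SMILES string.
#' @examples
#' gen_motif_molecule(list(motif_recipe("Cl_amideN_at_k", k = 5)), seed = 1)
#' @export
gen_motif_molecule <- function(recipes, seed = 1, gap = 14L, check = TRUE) {
  subs <- unlist(lapply(recipes, function(r) {
    rep(.motif_substituent(r), r$count)
  }))
  smiles <- withr::with_seed(seed, {
    if (length(subs) > 1L) subs <- sample(subs)
    # randomized branched alkyl tail for structural diversity
    tail_units <- sample(c("C", "C", "C(C)"), sample(2:8, 1L), replace = TRUE)
    tail <- paste(tail_units, collapse = "")
    if (length(subs) == 0L) {
      paste0("CC", tail)
    } else {
      paste0("CC",
             paste0(vapply(subs, function(s) paste0("C(", s, ")",
                                                    strrep("C", gap)),
                           character(1)),
                    collapse = ""),
             tail)
    }
  })
  if (check && length(recipes)) {
    mol <- parse_molecule(smiles)
    for (r in recipes) {
      ok <- switch(r$motif,
        Cl_amideN_at_k = proximity_value(mol, descriptor_spec(
          "chk", "proximity", target_class = "amideN", source_class = "Cl",
          k = r$k, mode = "exactly_k_excl")) >= r$count,
        sp2O_sp3O_at_k = proximity_value(mol, descriptor_spec(
          "chk", "proximity", target_class = "sp3O", source_class = "sp2O",
          k = r$k, mode = "exactly_k_excl")) >= r$count,
        aroN_ring = length(classify_atoms(mol, "aroN")) >= r$count,
        ring_with_positive_C =
          length(classify_atoms(mol, "ringCplus")) >= 1L
      )
      if (!ok) stop("motif not realized in generated molecule: ", r$motif)
    }
  }
  smiles
}

#' Generate a descriptor table with a planted sparse linear response
#'
#' Informative columns carry coefficients `beta`; decoys are independent of
#' the response. Column value distributions mimic the two descriptor
#' families: small non-negative integers (Poisson) for count-like columns
#' and bounded continuous values in [0, 1.5] for charge-sum-like columns
#' (every fifth column).
#'
#' @param n number of rows (molecules).
#' @param beta coefficients of the informative columns (default: the six
#'   published model coefficients).
#' @param beta0 intercept (default 6.176, the published model intercept).
#' @param p_decoy number of decoy columns.
#' @param sigma response noise standard deviation.
#' @param seed integer RNG seed.
#' @return list with `X` (matrix, informative columns named `true1..`,
#'   decoys `decoy1..`, in shuffled order), `y`, `true_names`, `beta`,
#'   `beta0`, `sigma`, `seed`.
#' @export
gen_planted_table <- function(n, beta = c(1.513, 0.519, 1.197, -1.018,
                                          -1.091, -0.9),
                              beta0 = 6.176, p_decoy = 194, sigma = 0.3,
                              seed = 1) {
  p_true <- length(beta)
  stopifnot(p_true >= 1L, n > p_true + 2L, sigma >= 0)
  withr::with_seed(seed, {
    p <- p_true + p_decoy
    gen_col <- function(j) {
      if (j %% 5L == 0L) runif(n, 0, 1.5) else rpois(n, lambda = runif(1, 0.4, 1.2))
    }
    X <- vapply(seq_len(p), gen_col, numeric(n))
    colnames(X) <- c(paste0("true", seq_len(p_true)),
                     if (p_decoy > 0L) paste0("decoy", seq_len(p_decoy)))
    X <- X[, sample.int(p), drop = FALSE]
    true_names <- paste0("true", seq_len(p_true))
    y <- beta0 + drop(X[, true_names, drop = FALSE] %*% beta) +
      rnorm(n, 0, sigma)
    list(X = X, y = y, true_names = true_names, beta = beta,
         beta0 = beta0, sigma = sigma, seed = seed)
  })
}

#' Generate a synthetic QSAR study (molecules + activities)
#'
#' Draws `n` molecules with random motif content (each motif present with
#' the given probability, distance motifs at their model distances plus
#' off-distance variants for contrast), computes the named descriptor set,
#' and assigns activities from the published-model linear combination of
#' the six model descriptors plus Gaussian noise on the pKi scale. Ki
#' values are back-transformed (`Ki = 10^(9 - pKi)` nM) so the set
#' round-trips through [curate()] and [to_pki()].
#'
#' @param n number of molecules.
#' @param sigma pKi noise standard deviation (default 0.3).
#' @param seed integer RNG seed.
#' @return list with `records` (data.frame `id`, `smiles`, `ki_nM`),
#'   `mols`, `X` (named descriptor matrix), `pki_true`.
#' @export
gen_qsar_dataset <- function(n, sigma = 0.3, seed = 1) {
  specs <- named_descriptor_set()
  model <- published_model()
  recipes_and_seeds <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      rec <- list()
      if (runif(1) < 0.5) rec <- c(rec, list(motif_recipe("Cl_amideN_at_k",
        k = sample(c(3L, 5L, 5L, 7L), 1L), count = sample(1:2, 1L))))
      if (runif(1) < 0.5) rec <- c(rec, list(motif_recipe("sp2O_sp3O_at_k",
        k = sample(c(4L, 6L, 6L, 8L), 1L), count = 1L)))
      if (runif(1) < 0.6) rec <- c(rec, list(motif_recipe("aroN_ring",
        count = sample(1:2, 1L))))
      list(recipes = rec, mol_seed = sample.int(1e6, 1L))
    })
  })
  smiles <- vapply(seq_len(n), function(i) {
    gen_motif_molecule(recipes_and_seeds[[i]]$recipes,
                       seed = recipes_and_seeds[[i]]$mol_seed, check = FALSE)
  }, character(1))
  ids <- sprintf("syn%03d", seq_len(n))
  mols <- parse_molecules(smiles, ids)
  X <- compute_matrix(mols, specs)
  pki_true <- unname(predict(model, X))
  noise <- withr::with_seed(seed + 1L, rnorm(n, 0, sigma))
  pki <- pki_true + noise
  list(
    records = data.frame(id = ids, smiles = smiles,
                         ki_nM = 10^(9 - pki), stringsAsFactors = FALSE),
    mols = mols, X = X, pki_true = pki_true
  )
}

#' Write a synthetic study in the input dialect of the pipeline
#'
#' Emits a `.smi` file (`smiles id` per line) and an activity CSV
#' (`id,smiles,ki_nM`), plus a truth JSON when a planted table is given.
#'
#' @param dataset result of [gen_qsar_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_synthetic_study <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste(dataset$records$smiles, dataset$records$id),
             file.path(dir, "molecules.smi"))
  write.csv(dataset$records, file.path(dir, "activities.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
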
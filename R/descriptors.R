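#' Declare a molecular descriptor
#'
#' Three descriptor kinds are supported:
#' \describe{
#'   \item{count}{number of atoms in `target_class`}
#'   \item{charge_sum}{sum of partial charges over atoms in `target_class`}
#'   \item{proximity}{counts relating a source atom class A and a counted
#'     target class B through the topological distance matrix. With
#'     `d(b) = min over a in A (a != b) of dist(a, b)`:
#'     `exactly_k_excl` counts target atoms whose *nearest* source atom is
#'     exactly `k` bonds away (a target atom with a source atom closer than
#'     `k` is excluded); `within_le_k` counts target atoms with
#'     `1 <= d(b) <= k`; `pairs_le_k` counts ordered (source, target) pairs
#'     at distance `1..k`.}
#' }
#'
#' @param name descriptor name (column name in the matrix).
#' @param kind one of `"count"`, `"charge_sum"`, `"proximity"`.
#' @param target_class atom class whose members are counted/summed
#'   (see [atom_class_names()]).
#' @param source_class anchor atom class A (proximity only).
#' @param k bond distance (proximity only, `k >= 1`).
#' @param mode `"exactly_k_excl"`, `"within_le_k"` or `"pairs_le_k"`.
#' @return a `descriptor_spec` object.
#' @export
descriptor_spec <- function(name, kind, target_class, source_class = NULL,
                            k = NULL, mode = NULL) {
  kind <- match.arg(kind, c("count", "charge_sum", "proximity"))
  if (kind == "proximity") {
    stopifnot(!is.null(source_class), !is.null(k), k >= 1)
    mode <- match.arg(mode, c("exactly_k_excl", "within_le_k", "pairs_le_k"))
  } else {
    source_class <- NULL; k <- NULL; mode <- NULL
  }
  structure(list(name = name, kind = kind, target_class = target_class,
                 source_class = source_class, k = k, mode = mode),
            class = "descriptor_spec")
}

#' The named descriptor set of the factor Xa model
#'
#' Returns the six descriptors of the published six-descriptor model plus
#' the ten comparator descriptors discussed alongside it:
#' `ringCplus_sumpc` (partial-charge sum over positively charged ring
#' carbons), `aroN_sp2C_4B` (aromatic N within 4 bonds of an sp2 carbon),
#' `fClamdN5B` (amide N exactly 5 bonds from the nearest chlorine),
#' `fsp2Osp3O6B`, `fsp2Nsp3O9B`, `fsp2Csp2O8B` (exact-distance frequencies),
#' and comparators `ringC`, `nCplus`, `naroC`, `naroCplus`, `aroN`, `nsp2C`
#' (plain counts), `aroN_sp2C_3B`, `aroN_sp2C_5B`, `sp3O_sp2O_6B`,
#' `sp3O_sp2N_9B` (within-k variants).
#'
#' @return named list of 16 [descriptor_spec()] objects.
#' @export
named_descriptor_set <- function() {
  specs <- list(
    # the six model descriptors
    descriptor_spec("ringCplus_sumpc", "charge_sum", "ringCplus"),
    descriptor_spec("aroN_sp2C_4B", "proximity", target_class = "aroN",
                    source_class = "sp2C", k = 4, mode = "within_le_k"),
    descriptor_spec("fClamdN5B", "proximity", target_class = "amideN",
                    source_class = "Cl", k = 5, mode = "exactly_k_excl"),
    descriptor_spec("fsp2Osp3O6B", "proximity", target_class = "sp3O",
                    source_class = "sp2O", k = 6, mode = "exactly_k_excl"),
    descriptor_spec("fsp2Nsp3O9B", "proximity", target_class = "sp3O",
                    source_class = "sp2N", k = 9, mode = "exactly_k_excl"),
    descriptor_spec("fsp2Csp2O8B", "proximity", target_class = "sp2O",
                    source_class = "sp2C", k = 8, mode = "exactly_k_excl"),
    # comparators
    descriptor_spec("ringC", "count", "ringC"),
    descriptor_spec("nCplus", "count", "Cplus"),
    descriptor_spec("naroC", "count", "aroC"),
    descriptor_spec("naroCplus", "count", "aroCplus"),
    descriptor_spec("aroN", "count", "aroN"),
    descriptor_spec("nsp2C", "count", "sp2C"),
    descriptor_spec("aroN_sp2C_3B", "proximity", target_class = "aroN",
                    source_class = "sp2C", k = 3, mode = "within_le_k"),
    descriptor_spec("aroN_sp2C_5B", "proximity", target_class = "aroN",
                    source_class = "sp2C", k = 5, mode = "within_le_k"),
    descriptor_spec("sp3O_sp2O_6B", "proximity", target_class = "sp3O",
                    source_class = "sp2O", k = 6, mode = "within_le_k"),
    descriptor_spec("sp3O_sp2N_9B", "proximity", target_class = "sp3O",
                    source_class = "sp2N", k = 9, mode = "within_le_k")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Evaluate a proximity descriptor on one molecule
#'
#' @param mol a `molgraph`.
#' @param spec a proximity [descriptor_spec()].
#' @return non-negative integer count (0 when either class is empty).
#' @export
proximity_value <- function(mol, spec) {
  stopifnot(inherits(spec, "descriptor_spec"), spec$kind == "proximity")
  A <- classify_atoms(mol, spec$source_class)
  B <- classify_atoms(mol, spec$target_class)
  if (!length(A) || !length(B)) return(0L)
  D <- mol$dist

  if (spec$mode == "pairs_le_k") {
    sub <- D[A, B, drop = FALSE]
    # exclude self-pairs for atoms in both classes (distance 0 never counts)
    return(sum(sub >= 1 & sub <= spec$k))
  }

  dmin <- vapply(B, function(b) {
    src <- setdiff(A, b)
    if (!length(src)) return(Inf)
    min(D[src, b])
  }, numeric(1))

  if (spec$mode == "exactly_k_excl") sum(dmin == spec$k)
  else sum(dmin >= 1 & dmin <= spec$k)
}

#' Sum partial charges over an atom class
#'
#' @param mol a `molgraph`.
#' @param cls atom class name.
#' @return sum of partial charges (0 when the class is empty).
#' @export
charge_sum_value <- function(mol, cls) {
  idx <- classify_atoms(mol, cls)
  if (!length(idx)) return(0)
  sum(mol$atoms$partial_charge[idx])
}

#' Evaluate any descriptor spec on one molecule
#' @inheritParams proximity_value
#' @export
descriptor_value <- function(mol, spec) {
  switch(spec$kind,
    count = length(classify_atoms(mol, spec$target_class)),
    charge_sum = charge_sum_value(mol, spec$target_class),
    proximity = proximity_value(mol, spec)
  )
}

#' Compute the molecules-by-descriptors matrix
#'
#' @param mols list of `molgraph` objects (order preserved in rows).
#' @param specs list of [descriptor_spec()] objects (order preserved in
#'   columns); defaults to [named_descriptor_set()].
#' @return numeric matrix with molecule ids as row names and descriptor
#'   names as column names; attribute `"provenance"` records the charge
#'   scheme and toolkit.
#' @export
compute_matrix <- function(mols, specs = named_descriptor_set()) {
  stopifnot(length(mols) > 0L)
  ids <- vapply(mols, `[[`, character(1), "id")
  X <- matrix(0, nrow = length(mols), ncol = length(specs),
              dimnames = list(ids, vapply(specs, `[[`, character(1), "name")))
  for (i in seq_along(mols)) {
    X[i, ] <- vapply(specs, function(s) as.numeric(descriptor_value(mols[[i]], s)),
                     numeric(1))
  }
  if (any(!is.finite(X))) {
    bad <- ids[apply(!is.finite(X), 1L, any)]
    stop("non-finite descriptor values for: ", paste(bad, collapse = ", "))
  }
  attr(X, "provenance") <- list(toolkit = "openbabel/ChemmineOB",
                                charges = "gasteiger")
  X
}

#' Read / write a JSON descriptor registry
#'
#' The registry is an array of objects with fields `name`, `kind`,
#' `target`, and for proximity descriptors `source`, `k`, `mode`.
#'
#' @param path JSON file path.
#' @return named list of [descriptor_spec()] objects.
#' @export
read_descriptor_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(r) {
    descriptor_spec(r$name, r$kind, target_class = r$target,
                    source_class = r$source, k = r$k, mode = r$mode)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' @rdname read_descriptor_registry
#' @param specs named list of descriptor specs.
#' @export
write_descriptor_registry <- function(specs, path) {
  out <- lapply(specs, function(s) {
    x <- list(name = s$name, kind = s$kind, target = s$target_class)
    if (s$kind == "proximity") {
      x$source <- s$source_class; x$k <- s$k; x$mode <- s$mode
    }
    x
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a descriptor matrix to CSV (first column `id`)
#' @param X matrix from [compute_matrix()].
#' @param path output path.
#' @export
write_descriptor_csv <- function(X, path) {
  df <- data.frame(id = rownames(X), as.data.frame(X), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
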
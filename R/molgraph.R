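#' @importFrom stats coef cor median predict quantile rnorm runif rpois sd var setNames
#' @importFrom utils head read.csv write.csv
NULL

# Elements considered "organic" for curation purposes; anything else is
# treated as a metal/organometallic and excluded.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

# SYBYL atom-type suffix -> hybridization label. Aromatic and planar/amide
# nitrogens are mapped to sp2 (conjugated lone pair), matching standard
# cheminformatics perception.
.SYBYL_HYB <- c(
  "1" = "sp", "2" = "sp2", "3" = "sp3", "ar" = "sp2", "am" = "sp2",
  "pl3" = "sp2", "cat" = "sp2", "co2" = "sp2", "4" = "sp3",
  "O" = "sp3", "O2" = "sp3", "t3p" = "sp3", "spc" = "sp3", "th" = "sp3"
)

# charge_scheme "none" skips charge assignment entirely (all charges zero);
# needed for species outside the Gasteiger parameter set, e.g. metal salts
# screened during curation.
.ob_options <- function(charge_scheme = "gasteiger") {
  if (identical(charge_scheme, "none")) {
    return(data.frame(names = character(0), args = character(0)))
  }
  data.frame(names = "partialcharge", args = charge_scheme,
             stringsAsFactors = FALSE)
}

# Run one batched OpenBabel conversion from SMILES. `ids` must be free of
# whitespace; internal surrogate ids are used and mapped back.
.ob_convert <- function(smiles, ids, to, options = NULL) {
  stopifnot(length(smiles) == length(ids))
  key <- sprintf("tq%06d", seq_along(smiles))
  src <- paste0(paste(smiles, key, collapse = "\n"), "\n")
  out <- if (is.null(options)) {
    ChemmineOB::convertFormat("SMI", to, source = src,
                              options = data.frame(names = character(0),
                                                   args = character(0)))
  } else {
    ChemmineOB::convertFormat("SMI", to, source = src, options = options)
  }
  list(out = out, key = key)
}

#' Parse SMILES strings into annotated molecular graphs
#'
#' Converts SMILES into hydrogen-suppressed molecular graphs annotated with
#' element, aromaticity, hybridization, ring membership, formal charge,
#' Gasteiger-Marsili partial charge, bond list and the all-pairs topological
#' distance matrix (bond counts along shortest heavy-atom paths; `Inf`
#' between disconnected fragments).
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional character vector of molecule identifiers (used in
#'   error messages and as names of the result). Defaults to `mol1..moln`.
#' @param charge_scheme partial-charge model passed to OpenBabel
#'   (default `"gasteiger"`; `"mmff94"` and `"eem"` are also understood).
#' @return For `parse_molecules`, a named list of `molgraph` objects; for
#'   `parse_molecule`, a single `molgraph`.
#' @examples
#' mol <- parse_molecule("c1ccncc1")
#' sum(mol$atoms$aromatic)
#' @export
parse_molecules <- function(smiles, ids = NULL, charge_scheme = "gasteiger") {
  if (length(smiles) == 0L) return(list())
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate molecule ids")

  conv <- .ob_convert(smiles, ids, "MOL2", options = .ob_options(charge_scheme))
  blocks <- .split_mol2(conv$out)
  can <- .ob_convert(smiles, ids, "CAN")
  can_map <- .parse_can(can$out)

  missing <- setdiff(conv$key, names(blocks))
  if (length(missing)) {
    stop("unparseable SMILES for id(s): ",
         paste(ids[match(missing, conv$key)], collapse = ", "))
  }

  mols <- vector("list", length(smiles))
  names(mols) <- ids
  for (i in seq_along(smiles)) {
    g <- .mol2_to_molgraph(blocks[[conv$key[i]]])
    g$smiles <- smiles[i]
    g$canonical_smiles <- unname(can_map[conv$key[i]])
    g$id <- ids[i]
    mols[[i]] <- g
  }
  mols
}

#' @rdname parse_molecules
#' @export
parse_molecule <- function(smiles, ids = NULL, charge_scheme = "gasteiger") {
  stopifnot(length(smiles) == 1L)
  parse_molecules(smiles, ids, charge_scheme)[[1L]]
}

# Split concatenated MOL2 text into named per-molecule blocks.
.split_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  starts <- grep("@<TRIPOS>MOLECULE", lines, fixed = TRUE)
  if (!length(starts)) return(structure(list(), names = character(0)))
  ends <- c(starts[-1L] - 1L, length(lines))
  blocks <- lapply(seq_along(starts),
                   function(i) lines[starts[i]:ends[i]])
  names(blocks) <- vapply(blocks, function(b) trimws(b[2L]), character(1))
  blocks
}

.parse_can <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  can <- vapply(parts, `[`, character(1), 1L)
  key <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", character(1))
  setNames(can, key)
}

# Build a molgraph from one MOL2 block (vector of lines).
.mol2_to_molgraph <- function(lines) {
  sect <- function(tag) {
    i <- grep(paste0("@<TRIPOS>", tag), lines, fixed = TRUE)
    if (!length(i)) return(character(0))
    j <- grep("@<TRIPOS>", lines, fixed = TRUE)
    nxt <- j[j > i[1L]]
    end <- if (length(nxt)) nxt[1L] - 1L else length(lines)
    if (end < i[1L] + 1L) return(character(0))
    lines[(i[1L] + 1L):end]
  }

  counts <- as.integer(strsplit(trimws(lines[3L]), "[ \t]+")[[1L]])
  n_atoms <- counts[1L]

  atom_lines <- head(sect("ATOM"), n_atoms)
  af <- strsplit(trimws(atom_lines), "[ \t]+")
  sybyl <- vapply(af, `[`, character(1), 6L)
  pcharge <- as.numeric(vapply(af, `[`, character(1), 9L))
  element <- sub("\\..*$", "", sybyl)
  suffix <- ifelse(grepl(".", sybyl, fixed = TRUE),
                   sub("^[^.]*\\.", "", sybyl), "")
  hyb <- unname(.SYBYL_HYB[suffix])
  hyb[is.na(hyb)] <- "other"

  bond_lines <- sect("BOND")
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "[ \t]+")
    bonds <- data.frame(
      i = as.integer(vapply(bf, `[`, character(1), 2L)),
      j = as.integer(vapply(bf, `[`, character(1), 3L)),
      order = vapply(bf, `[`, character(1), 4L),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                        stringsAsFactors = FALSE)
  }

  g <- igraph::make_empty_graph(n = n_atoms, directed = FALSE)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  }
  dist <- igraph::distances(g)
  in_ring <- rep(FALSE, n_atoms)
  if (nrow(bonds)) {
    bridge_ids <- igraph::bridges(g)
    cyc_edges <- setdiff(seq_len(nrow(bonds)), as.integer(bridge_ids))
    in_ring[unique(c(bonds$i[cyc_edges], bonds$j[cyc_edges]))] <- TRUE
  }

  # Aromaticity: atoms typed *.ar, plus ring atoms on MOL2 "ar" bonds
  # (covers pyrrole-type N.pl3 members of aromatic rings). Acyclic atoms on
  # "ar" bonds are SYBYL carboxylate/amidinium notation, not aromatic.
  aromatic <- grepl("\\.ar$", sybyl)
  if (nrow(bonds)) {
    ar <- bonds$order == "ar"
    on_ar <- unique(c(bonds$i[ar], bonds$j[ar]))
    aromatic[intersect(on_ar, which(in_ring))] <- TRUE
  }
  hyb[aromatic] <- "sp2"

  # formal charges live in UNITY_ATOM_ATTR sub-blocks
  formal <- integer(n_atoms)
  attr_lines <- sect("UNITY_ATOM_ATTR")
  k <- 1L
  while (k <= length(attr_lines)) {
    hd <- as.integer(strsplit(trimws(attr_lines[k]), "[ \t]+")[[1L]])
    if (length(hd) < 2L || is.na(hd[1L])) break
    for (a in seq_len(hd[2L])) {
      kv <- strsplit(trimws(attr_lines[k + a]), "[ \t]+")[[1L]]
      if (identical(kv[1L], "charge")) formal[hd[1L]] <- as.integer(kv[2L])
    }
    k <- k + 1L + hd[2L]
  }

  structure(list(
    atoms = data.frame(
      element = element, aromatic = aromatic, hybridization = hyb,
      in_ring = in_ring, formal_charge = formal, partial_charge = pcharge,
      stringsAsFactors = FALSE
    ),
    bonds = bonds,
    dist = dist,
    canonical_smiles = NA_character_,
    smiles = NA_character_,
    id = NA_character_
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$id, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  cat("  smiles: ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Atom classes used by the proximity descriptors
#'
#' Returns the names of the supported atom classes. Each class is a
#' predicate over annotated atoms of a [parse_molecule()] graph:
#' \describe{
#'   \item{ringC / ringCplus}{carbon in a ring / additionally carrying a
#'     strictly positive partial charge}
#'   \item{Cplus}{carbon with partial charge > 0}
#'   \item{aroC / aroCplus}{aromatic carbon / positively charged aromatic carbon}
#'   \item{aroN}{aromatic nitrogen}
#'   \item{sp2C, sp2N, sp2O, sp3O}{element at the stated hybridization
#'     (aromatic atoms count as sp2)}
#'   \item{amideN}{nitrogen single-bonded to a carbon bearing a double-bonded
#'     oxygen}
#'   \item{Cl}{chlorine}
#' }
#' @return character vector of class names.
#' @export
atom_class_names <- function() {
  c("ringC", "Cplus", "aroC", "aroCplus", "aroN", "sp2C", "sp3O",
    "sp2O", "sp2N", "amideN", "Cl", "ringCplus")
}

#' Classify atoms of a molecular graph
#'
#' @param mol a `molgraph` from [parse_molecule()].
#' @param cls one of [atom_class_names()].
#' @return integer vector of (1-based) atom indices satisfying the class
#'   predicate; possibly empty.
#' @examples
#' classify_atoms(parse_molecule("c1ccncc1"), "aroN")
#' @export
classify_atoms <- function(mol, cls) {
  stopifnot(inherits(mol, "molgraph"))
  a <- mol$atoms
  idx <- switch(cls,
    ringC     = a$element == "C" & a$in_ring,
    Cplus     = a$element == "C" & a$partial_charge > 0,
    ringCplus = a$element == "C" & a$in_ring & a$partial_charge > 0,
    aroC      = a$element == "C" & a$aromatic,
    aroCplus  = a$element == "C" & a$aromatic & a$partial_charge > 0,
    aroN      = a$element == "N" & a$aromatic,
    sp2C      = a$element == "C" & a$hybridization == "sp2",
    sp3O      = a$element == "O" & a$hybridization == "sp3",
    sp2O      = a$element == "O" & a$hybridization == "sp2",
    sp2N      = a$element == "N" & a$hybridization == "sp2",
    amideN    = .amide_nitrogens(mol),
    Cl        = a$element == "Cl",
    stop("unknown atom class: ", cls)
  )
  which(idx)
}

# amide N: nitrogen with a single (non-aromatic) bond to a carbon that has a
# double bond to oxygen.
.amide_nitrogens <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  out <- rep(FALSE, nrow(a))
  if (!nrow(b)) return(out)
  dbl_co <- unique(c(
    b$i[b$order == "2" & a$element[b$i] == "C" & a$element[b$j] == "O"],
    b$j[b$order == "2" & a$element[b$j] == "C" & a$element[b$i] == "O"]
  ))
  single <- b$order %in% c("1", "am")
  for (r in which(single)) {
    i <- b$i[r]; j <- b$j[r]
    if (a$element[i] == "N" && j %in% dbl_co) out[i] <- TRUE
    if (a$element[j] == "N" && i %in% dbl_co) out[j] <- TRUE
  }
  out
}

#' Transform an inhibition constant to its negative log-molar value
#'
#' `pKi = -log10(Ki[nM] * 1e-9)`; higher values mean stronger inhibition.
#'
#' @param ki_nM inhibition constant in nanomolar; must be > 0.
#' @return pKi on the molar scale.
#' @examples
#' to_pki(1)      # 9
#' to_pki(0.007)  # 11.155
#' @export
to_pki <- function(ki_nM) {
  ki_nM <- as.numeric(ki_nM)
  if (any(!is.finite(ki_nM)) || any(ki_nM <= 0)) {
    stop("Ki must be a positive, finite value (nM)")
  }
  -log10(ki_nM * 1e-9)
}
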
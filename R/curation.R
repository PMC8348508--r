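#' Curate raw activity records
#'
#' Applies the standard QSAR curation rules to a raw table of SMILES and
#' inhibition constants: entries with missing, non-numeric or qualified Ki
#' values (e.g. `">100"`, `"<5"`, `"~10"`) are dropped; salt/solvate
#' fragments are stripped by keeping the fragment with the most heavy atoms;
#' molecules containing metals (any element outside H, B, C, N, O, F, Si, P,
#' S, Cl, Se, Br, I) are dropped; duplicates are removed by canonical SMILES
#' keeping the first occurrence; pKi is computed for the survivors.
#'
#' Curation parses molecules without partial-charge assignment (charges play
#' no role in any curation rule, and metal species lie outside the
#' Gasteiger parameter set).
#'
#' @param records data.frame with columns `id`, `smiles` and `ki_nM`
#'   (`ki_nM` may be character and carry qualifiers).
#' @return data.frame with columns `id`, `canonical_smiles`, `ki_nM`, `pki`
#'   (one row per surviving unique molecule).
#' @export
curate <- function(records) {
  if (!"smiles" %in% names(records) && "canonical_smiles" %in% names(records)) {
    records$smiles <- records$canonical_smiles
  }
  stopifnot(all(c("id", "smiles", "ki_nM") %in% names(records)))
  id <- as.character(records$id)
  smi <- as.character(records$smiles)
  ki_raw <- as.character(records$ki_nM)

  # Ki must be plain positive numbers: no qualifiers, no blanks
  ki <- suppressWarnings(as.numeric(gsub(",", "", trimws(ki_raw))))
  keep <- !is.na(ki) & ki > 0 & !grepl("[<>~]", ki_raw) &
    nzchar(trimws(smi)) & !is.na(smi)
  id <- id[keep]; smi <- smi[keep]; ki <- ki[keep]
  if (!length(id)) stop("curation removed every record (no usable Ki values)")

  smi <- vapply(smi, .strip_salt, character(1), USE.NAMES = FALSE)

  # charge-free parse: metal species have no Gasteiger parameters but must
  # still be perceived so they can be excluded
  mols <- parse_molecules(smi, ids = id, charge_scheme = "none")
  organic <- vapply(mols, function(m) {
    all(m$atoms$element %in% .ORGANIC_ELEMENTS)
  }, logical(1))
  mols <- mols[organic]
  id <- id[organic]; ki <- ki[organic]
  if (!length(id)) stop("curation removed every record (all metal-bearing)")

  can <- vapply(mols, `[[`, character(1), "canonical_smiles")
  first <- !duplicated(can)

  data.frame(
    id = id[first],
    canonical_smiles = unname(can[first]),
    ki_nM = ki[first],
    pki = to_pki(ki[first]),
    stringsAsFactors = FALSE
  )
}

# Keep the fragment with the most heavy atoms (first on ties). Heavy-atom
# counts come from the parsed fragments so bracket atoms, two-letter
# elements and aromatic lowercase symbols are all counted correctly.
.strip_salt <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1L]]
  if (length(frags) == 1L) return(smiles)
  mols <- parse_molecules(frags, ids = paste0("frag", seq_along(frags)),
                          charge_scheme = "none")
  sizes <- vapply(mols, function(m) nrow(m$atoms), integer(1))
  frags[which.max(sizes)]
}

#' Read activity data
#'
#' `read_activity_csv` reads a CSV with header `id,smiles,ki_nM`;
#' `read_smi` reads a whitespace-separated SMILES file (`smiles id` per
#' line, Ki absent and set to `NA`).
#'
#' @param path file path.
#' @return data.frame with columns `id`, `smiles`, `ki_nM`.
#' @export
read_activity_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("id", "smiles", "ki_nM") %in% names(df)))
  df[c("id", "smiles", "ki_nM")]
}

#' @rdname read_activity_csv
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                character(1)),
    smiles = vapply(parts, `[`, character(1), 1L),
    ki_nM = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write a curated activity table
#'
#' pKi values are exported with three decimals.
#'
#' @param curated data.frame from [curate()].
#' @param path output CSV path.
#' @export
write_curated_csv <- function(curated, path) {
  out <- curated
  out$pki <- sprintf("%.3f", out$pki)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
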
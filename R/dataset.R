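#' Objective feature selection: prune constant and collinear descriptors
#'
#' Removes (in order) zero-variance columns, near-constant columns whose
#' most frequent value occupies more than `1 - near_const_tol` of the rows,
#' and then one member of every pair with absolute Pearson correlation above
#' `corr_cut`. Pairs are visited in decreasing |R| for determinism; within a
#' pair the column with the lower |correlation to `y`| is dropped when `y`
#' is supplied, otherwise the later column.
#'
#' @param X numeric descriptor matrix (rows = molecules).
#' @param y optional response used to break correlation ties.
#' @param corr_cut pairwise |R| threshold (default 0.90).
#' @param near_const_tol near-constancy tolerance (default 0.05: columns
#'   where >= 95% of rows share one value are removed).
#' @return the filtered matrix, with attribute `"removed"` naming the
#'   discarded columns and the reason.
#' @export
ofs_filter <- function(X, y = NULL, corr_cut = 0.90, near_const_tol = 0.05) {
  stopifnot(nrow(X) >= 2L)
  X <- as.matrix(X)
  removed <- list()
  note <- function(nm, why) {
    removed[[length(removed) + 1L]] <<- data.frame(name = nm, reason = why,
                                                   stringsAsFactors = FALSE)
  }

  const <- apply(X, 2L, function(v) var(v) == 0)
  if (any(const)) note(colnames(X)[const], "constant")
  X <- X[, !const, drop = FALSE]

  maxfreq <- apply(X, 2L, function(v) max(table(v)) / length(v))
  nearc <- maxfreq > (1 - near_const_tol)
  if (any(nearc)) note(colnames(X)[nearc], "near_constant")
  X <- X[, !nearc, drop = FALSE]
  if (!ncol(X)) stop("objective feature selection removed every descriptor")

  R <- suppressWarnings(cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  ry <- if (!is.null(y)) abs(suppressWarnings(cor(X, y)))[, 1L] else NULL

  pairs <- which(abs(R) > corr_cut & upper.tri(R), arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(R[pairs]), pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]
    alive <- rep(TRUE, ncol(X))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (!alive[i] || !alive[j]) next
      drop_j <- if (!is.null(ry)) {
        yi <- ifelse(is.na(ry[i]), 0, ry[i]); yj <- ifelse(is.na(ry[j]), 0, ry[j])
        yj <= yi   # keep the column better correlated to the response
      } else TRUE  # keep the earlier column
      if (drop_j) alive[j] <- FALSE else alive[i] <- FALSE
    }
    if (any(!alive)) note(colnames(X)[!alive], "collinear")
    X <- X[, alive, drop = FALSE]
  }
  if (!ncol(X)) stop("objective feature selection removed every descriptor")
  attr(X, "removed") <- if (length(removed)) do.call(rbind, removed) else
    data.frame(name = character(0), reason = character(0))
  X
}

#' Split molecules into training and external validation sets
#'
#' Uniformly random, seed-reproducible split. The training size is
#' `round(train_fraction * n)`.
#'
#' @param n number of molecules.
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer RNG seed.
#' @return character vector of length `n` with values `"train"` /
#'   `"external"`.
#' @examples
#' table(split_dataset(1121, 0.8, seed = 1))  # 897 train, 224 external
#' @export
split_dataset <- function(n, train_fraction = 0.8, seed) {
  stopifnot(n >= 5L, train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * n)
  if (n_train < 1L || n_train >= n) stop("degenerate split sizes")
  labels <- rep("external", n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  labels[idx] <- "train"
  labels
}

#' Assemble a modeling table
#'
#' Binds curated records, descriptor matrix, response and split labels into
#' one object consumed by the selection and validation stages.
#'
#' @param records curated data.frame from [curate()].
#' @param X descriptor matrix aligned 1:1 with `records` rows.
#' @param split character vector of `"train"`/`"external"` labels.
#' @param seed the seed that generated `split` (recorded for provenance).
#' @return a `modeling_table` list with elements `records`, `X`, `y`,
#'   `split`, `seed`.
#' @export
modeling_table <- function(records, X, split, seed = NA_integer_) {
  stopifnot(nrow(records) == nrow(X), length(split) == nrow(X),
            all(split %in% c("train", "external")))
  structure(list(records = records, X = as.matrix(X), y = records$pki,
                 split = split, seed = seed),
            class = "modeling_table")
}

#' @export
print.modeling_table <- function(x, ...) {
  cat("<modeling_table> ", nrow(x$X), " molecules x ", ncol(x$X),
      " descriptors (", sum(x$split == "train"), " train / ",
      sum(x$split == "external"), " external)\n", sep = "")
  invisible(x)
}

#' Write a split-membership file
#' @param ids molecule ids.
#' @param split labels from [split_dataset()].
#' @param path output CSV path.
#' @export
write_split_csv <- function(ids, split, path) {
  write.csv(data.frame(id = ids, set = split), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
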
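#' Leave-one-out cross-validation statistics
#'
#' Leave-one-out predictions are obtained through the PRESS identity
#' `e_i / (1 - h_i)` (prediction residual from the full-fit residual and
#' leverage), which is algebraically identical to n refits for OLS. Rows
#' with leverage numerically equal to 1 fall back to an explicit refit
#' without that row.
#'
#' @param X training descriptor matrix.
#' @param y training response.
#' @param names descriptor names.
#' @return list with `q2` (`1 - PRESS/SStot`), `rmse_cv`, `ccc_cv`, and the
#'   LOO predictions `pred`.
#' @export
q2_loo <- function(X, y, names = colnames(X)) {
  X <- as.matrix(X)
  core <- .ols_core(X, y)
  if (is.null(core)) stop("singular design matrix in q2_loo")
  press_resid <- core$resid / (1 - core$h)
  exact1 <- which(core$h >= 1 - 1e-10)
  for (i in exact1) {
    m <- fit_mlr(X[-i, , drop = FALSE], y[-i], names)
    press_resid[i] <- y[i] - predict(m, X[i, , drop = FALSE])
  }
  pred <- y - press_resid
  sst <- sum((y - mean(y))^2)
  list(q2 = 1 - sum(press_resid^2) / sst,
       rmse_cv = sqrt(mean(press_resid^2)),
       ccc_cv = ccc(y, pred),
       pred = pred)
}

#' Leave-many-out cross-validation
#'
#' Each iteration leaves out `round(leave_fraction * n)` randomly chosen
#' rows, refits on the remainder and predicts the left-out rows. Squared
#' prediction errors are aggregated over all iterations against squared
#' deviations from the full training mean, so with `leave_fraction = 1/n`
#' and iterations covering every row once the statistic reduces exactly to
#' `Q2_LOO`.
#'
#' @param X,y,names as in [q2_loo()].
#' @param leave_fraction fraction left out per round (in (0, 0.5]).
#' @param iterations number of leave-many-out rounds.
#' @param seed integer RNG seed.
#' @param groups optional list of index vectors overriding random draws
#'   (used for exhaustive correspondence checks).
#' @return Q2_LMO (single numeric).
#' @export
q2_lmo <- function(X, y, names = colnames(X), leave_fraction = 0.3,
                   iterations = 1000, seed = 1, groups = NULL) {
  stopifnot(leave_fraction > 0, leave_fraction <= 0.5 || !is.null(groups))
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  n_out <- max(1L, round(leave_fraction * n))
  if (n - n_out < p + 2L) stop("leave-many-out group leaves too few training rows")
  if (is.null(groups)) {
    groups <- withr::with_seed(seed, replicate(iterations, sample.int(n, n_out),
                                               simplify = FALSE))
  }
  ybar <- mean(y)
  press <- 0; sstot <- 0
  for (g in groups) {
    m <- fit_mlr(X[-g, , drop = FALSE], y[-g], names)
    e <- y[g] - predict(m, X[g, , drop = FALSE])
    press <- press + sum(e^2)
    sstot <- sstot + sum((y[g] - ybar)^2)
  }
  1 - press / sstot
}

#' External validation statistics
#'
#' Computes the external prediction block: `rmse_ex`, `mae_ex`, `r2_ex`
#' (squared Pearson correlation between observed and predicted),
#' `q2_f1 = 1 - SSE/Σ(y - ȳ_tr)²`, `q2_f2` (same with the external mean),
#' `q2_f3 = 1 - (SSE/n_ext)/(SStot_tr/n_tr)`, `ccc_ex`, and the
#' through-origin diagnostics: slopes `k = Σ(y·ŷ)/Σ(ŷ²)` (observed on
#' predicted) and `kp = Σ(y·ŷ)/Σ(y²)` (predicted on observed), through-origin
#' determination coefficients `ro2 = 1 - Σ(y - kŷ)²/Σ(y - ȳ)²` and
#' `rpo2 = 1 - Σ(ŷ - kp·y)²/Σ(ŷ - ŷ̄)²`, the `1 - r²/ro²` terms and the
#' `r2m` pair `r² (1 - sqrt(r² - ro²))`.
#'
#' @param model an `mlr_model`.
#' @param X_ext,y_ext external descriptor matrix and observed response.
#' @param y_train training response (reference mean/variance for F1/F3).
#' @return named list of external statistics.
#' @export
external_stats <- function(model, X_ext, y_ext, y_train) {
  stopifnot(length(y_ext) >= 2L)
  yhat <- predict(model, X_ext)
  sse <- sum((y_ext - yhat)^2)
  n_ext <- length(y_ext); n_tr <- length(y_train)
  sst_tr_mean <- sum((y_ext - mean(y_train))^2)
  sst_ext <- sum((y_ext - mean(y_ext))^2)
  r2_ex <- if (sst_ext == 0) NA_real_ else
    suppressWarnings(cor(y_ext, yhat))^2

  k <- sum(y_ext * yhat) / sum(yhat^2)
  kp <- sum(y_ext * yhat) / sum(y_ext^2)
  ro2 <- 1 - sum((y_ext - k * yhat)^2) / sst_ext
  rpo2 <- 1 - sum((yhat - kp * y_ext)^2) / sum((yhat - mean(yhat))^2)
  rm2 <- r2_ex * (1 - sqrt(pmax(0, r2_ex - ro2)))
  rpm2 <- r2_ex * (1 - sqrt(pmax(0, r2_ex - rpo2)))

  list(
    rmse_ex = sqrt(sse / n_ext),
    mae_ex = mean(abs(y_ext - yhat)),
    r2_ex = r2_ex,
    q2_f1 = 1 - sse / sst_tr_mean,
    q2_f2 = if (sst_ext == 0) NA_real_ else 1 - sse / sst_ext,
    q2_f3 = 1 - (sse / n_ext) / (sum((y_train - mean(y_train))^2) / n_tr),
    ccc_ex = ccc(y_ext, yhat),
    k = k, kp = kp, ro2 = ro2, rpo2 = rpo2,
    one_minus_r2_ro2 = 1 - r2_ex / ro2,
    one_minus_r2_rpo2 = 1 - r2_ex / rpo2,
    r2m = rm2, rp2m = rpm2,
    pred = yhat
  )
}

#' Y-scrambling (response randomization)
#'
#' Refits the model on permuted responses to detect chance correlation. The
#' identity permutation is excluded from the draws. For every iteration the
#' training R2, the PRESS-based Q2_LOO and the Kxy multivariate correlation
#' of the scrambled [X, y] block are recorded.
#'
#' @param X,y,names as in [q2_loo()].
#' @param n_iter number of scrambling rounds (>= 100).
#' @param seed integer RNG seed.
#' @return list with `r2_mean`, `q2_mean`, `r2_max`, `q2_max`, `kxy` (of
#'   the unscrambled block) and the per-iteration data.frame `table`
#'   (columns `iter`, `kxy`, `r2`, `q2`).
#' @export
y_scramble <- function(X, y, names = colnames(X), n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 100L)
  X <- as.matrix(X)
  n <- nrow(X)
  perms <- withr::with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      repeat {
        p <- sample.int(n)
        if (!identical(p, seq_len(n))) return(p)
      }
    })
  })
  rows <- lapply(seq_len(n_iter), function(i) {
    ys <- y[perms[[i]]]
    core <- .ols_core(X, ys)
    if (is.null(core)) return(data.frame(iter = i, kxy = NA, r2 = NA, q2 = NA))
    sst <- sum((ys - mean(ys))^2)
    r2s <- 1 - sum(core$resid^2) / sst
    press <- sum((core$resid / (1 - core$h))^2)
    data.frame(iter = i, kxy = k_xy(X, ys), r2 = r2s, q2 = 1 - press / sst)
  })
  tab <- do.call(rbind, rows)
  list(r2_mean = mean(tab$r2, na.rm = TRUE),
       q2_mean = mean(tab$q2, na.rm = TRUE),
       r2_max = max(tab$r2, na.rm = TRUE),
       q2_max = max(tab$q2, na.rm = TRUE),
       kxy = k_xy(X, y),
       table = tab)
}

#' Multivariate K correlation index
#'
#' Todeschini's K index of total correlation of a variable block, computed
#' from the eigenvalues of the correlation matrix:
#' `K = sum(|lambda_i / sum(lambda) - 1/p|) / (2 (p - 1) / p)`. `k_xy(X, y)`
#' appends the response to the block; `k_xy(X)` measures the descriptor
#' block alone. 0 = no correlation, 1 = perfectly collinear block.
#'
#' @param X numeric matrix.
#' @param y optional response appended as an extra column.
#' @return K in [0, 1].
#' @export
k_xy <- function(X, y = NULL) {
  M <- if (is.null(y)) as.matrix(X) else cbind(as.matrix(X), y)
  C <- suppressWarnings(cor(M))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  lam <- abs(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  p <- ncol(M)
  sum(abs(lam / sum(lam) - 1 / p)) / (2 * (p - 1) / p)
}

#' Williams-plot applicability domain
#'
#' Leverages are computed from the training design matrix (with intercept):
#' `h_i = x_i' (X'X)^-1 x_i`; the warning threshold is `h* = 3 (p + 1) / n`.
#' Standardized residuals are raw residuals divided by the model residual
#' standard deviation `s`. A molecule is flagged a response outlier when
#' `|std_residual| > resid_cut` and structurally influential when `h > h*`.
#'
#' @param model an `mlr_model` fitted on the training rows.
#' @param X_train,y_train training data used for the fit.
#' @param X_ext,y_ext optional external set, projected onto the training
#'   `(X'X)^-1`.
#' @param resid_cut standardized-residual cutoff (default 2.5).
#' @return list with `h_star` and data.frame `table` (columns `id`, `set`,
#'   `leverage`, `std_residual`, `outlier`, `influential`).
#' @export
williams_ad <- function(model, X_train, y_train, X_ext = NULL, y_ext = NULL,
                        resid_cut = 2.5) {
  X_train <- as.matrix(X_train)
  take <- function(M) {
    if (length(model$descriptors) == 0L)
      matrix(numeric(0), nrow(M), 0L) else
        M[, model$descriptors, drop = FALSE]
  }
  Xi <- cbind(1, take(X_train))
  XtX <- crossprod(Xi)
  R <- tryCatch(chol(XtX), error = function(e)
    stop("singular X'X in applicability-domain computation"))
  XtXinv <- chol2inv(R)
  lev <- function(M) rowSums((M %*% XtXinv) * M)
  n <- nrow(Xi); p <- length(model$descriptors)
  h_star <- 3 * (p + 1) / n

  h_tr <- lev(Xi)
  e_tr <- y_train - predict(model, X_train)
  ids_tr <- rownames(X_train)
  if (is.null(ids_tr)) ids_tr <- paste0("train", seq_len(n))
  tab <- data.frame(id = ids_tr, set = "train", leverage = h_tr,
                    std_residual = e_tr / model$s, stringsAsFactors = FALSE)

  if (!is.null(X_ext)) {
    X_ext <- as.matrix(X_ext)
    Xe <- cbind(1, take(X_ext))
    h_ex <- lev(Xe)
    e_ex <- if (is.null(y_ext)) rep(NA_real_, nrow(Xe)) else
      y_ext - predict(model, X_ext)
    ids_ex <- rownames(X_ext)
    if (is.null(ids_ex)) ids_ex <- paste0("ext", seq_len(nrow(Xe)))
    tab <- rbind(tab, data.frame(id = ids_ex, set = "external",
                                 leverage = h_ex,
                                 std_residual = e_ex / model$s,
                                 stringsAsFactors = FALSE))
  }
  tab$outlier <- abs(tab$std_residual) > resid_cut
  tab$influential <- tab$leverage > h_star
  rownames(tab) <- NULL
  list(h_star = h_star, table = tab)
}

#' Full validation report for an MLR model
#'
#' Bundles the training, cross-validation, Y-scrambling, external and
#' applicability-domain statistics into one report.
#'
#' @param X_train,y_train training data.
#' @param X_ext,y_ext external data (may be NULL to skip the external
#'   block).
#' @param names descriptor names to model (default all columns).
#' @param lmo_fraction,lmo_iterations leave-many-out settings.
#' @param yscr_iterations Y-scrambling rounds.
#' @param resid_cut Williams-plot residual cutoff.
#' @param seed integer RNG seed for LMO and scrambling.
#' @return a `validation_report` list with elements `model`, `training`,
#'   `cv`, `yscr`, `external`, `ad`.
#' @export
validate_model <- function(X_train, y_train, X_ext = NULL, y_ext = NULL,
                           names = colnames(X_train), lmo_fraction = 0.3,
                           lmo_iterations = 1000, yscr_iterations = 1000,
                           resid_cut = 2.5, seed = 1) {
  X_train <- as.matrix(X_train)[, names, drop = FALSE]
  model <- fit_mlr(X_train, y_train, names)
  yhat <- predict(model, X_train)
  n <- length(y_train); p <- length(names)
  r2_tr <- r2(y_train, yhat)
  ssreg <- sum((yhat - mean(y_train))^2)
  ssres <- sum((y_train - yhat)^2)

  loo <- q2_loo(X_train, y_train, names)
  lmo <- q2_lmo(X_train, y_train, names, leave_fraction = lmo_fraction,
                iterations = lmo_iterations, seed = seed)
  ysc <- y_scramble(X_train, y_train, names, n_iter = yscr_iterations,
                    seed = seed + 1L)

  ext <- NULL
  if (!is.null(X_ext) && nrow(as.matrix(X_ext)) > 0L) {
    X_ext <- as.matrix(X_ext)[, names, drop = FALSE]
    ext <- external_stats(model, X_ext, y_ext, y_train)
  }
  ad <- williams_ad(model, X_train, y_train, X_ext, y_ext,
                    resid_cut = resid_cut)

  structure(list(
    model = model,
    training = list(
      R2_tr = r2_tr,
      R2_adj = 1 - (1 - r2_tr) * (n - 1) / (n - p - 1),
      RMSE_tr = rmse(y_train, yhat),
      MAE_tr = mae(y_train, yhat),
      s = model$s,
      F = (ssreg / p) / (ssres / (n - p - 1)),
      CCC_tr = ccc(y_train, yhat),
      Kxy = k_xy(X_train, y_train),
      Kx = k_xy(X_train),
      n_train = n
    ),
    cv = list(Q2_LOO = loo$q2, RMSE_cv = loo$rmse_cv, CCC_cv = loo$ccc_cv,
              Q2_LMO = lmo),
    yscr = list(R2_Yscr = ysc$r2_mean, Q2_Yscr = ysc$q2_mean,
                R2_Yscr_max = ysc$r2_max, Q2_Yscr_max = ysc$q2_max,
                iterations = yscr_iterations, table = ysc$table),
    external = ext,
    ad = ad,
    seed = seed
  ), class = "validation_report")
}

#' Serialize a validation report to JSON
#'
#' Statistic names follow the conventional QSAR notation (R2_tr, Q2_LOO,
#' Q2_LMO, CCC_tr, Q2_F1, ...). Large per-molecule tables are written as
#' arrays.
#'
#' @param report a `validation_report`.
#' @param path output JSON path.
#' @export
write_validation_report <- function(report, path) {
  ext <- report$external
  out <- list(
    descriptors = report$model$descriptors,
    coefficients = as.list(report$model$coef),
    coefficient_se = as.list(report$model$se),
    R2_tr = report$training$R2_tr,
    R2_adj = report$training$R2_adj,
    RMSE_tr = report$training$RMSE_tr,
    MAE_tr = report$training$MAE_tr,
    s = report$training$s,
    F = report$training$F,
    CCC_tr = report$training$CCC_tr,
    Kxy = report$training$Kxy,
    Kx = report$training$Kx,
    Q2_LOO = report$cv$Q2_LOO,
    RMSE_cv = report$cv$RMSE_cv,
    CCC_cv = report$cv$CCC_cv,
    Q2_LMO = report$cv$Q2_LMO,
    R2_Yscr = report$yscr$R2_Yscr,
    Q2_Yscr = report$yscr$Q2_Yscr,
    h_star = report$ad$h_star,
    seed = report$seed
  )
  if (!is.null(ext)) {
    out <- c(out, list(
      RMSE_ex = ext$rmse_ex, MAE_ex = ext$mae_ex, R2_ex = ext$r2_ex,
      Q2_F1 = ext$q2_f1, Q2_F2 = ext$q2_f2, Q2_F3 = ext$q2_f3,
      CCC_ex = ext$ccc_ex, k = ext$k, k_prime = ext$kp,
      Ro2 = ext$ro2, Rpo2 = ext$rpo2,
      one_minus_r2_ro2 = ext$one_minus_r2_ro2,
      one_minus_r2_rpo2 = ext$one_minus_r2_rpo2,
      r2m = ext$r2m, rp2m = ext$rp2m
    ))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
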
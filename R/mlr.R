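# Internal fast OLS core used by both fit_mlr and the GA fitness.
# Returns NULL on a singular design instead of raising.
.ols_core <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p1 <- ncol(Xi)
  qr_ <- qr(Xi)
  if (qr_$rank < p1) return(NULL)
  beta <- qr.coef(qr_, y)
  fitted <- drop(Xi %*% beta)
  e <- y - fitted
  Q <- qr.Q(qr_)
  h <- rowSums(Q * Q)
  list(beta = beta, fitted = fitted, resid = e, h = h, qr = qr_, p1 = p1)
}

#' Fit an ordinary least squares multilinear regression model
#'
#' @param X numeric matrix of descriptor values (training rows).
#' @param y numeric response (pKi).
#' @param names descriptor names (default `colnames(X)`).
#' @return an `mlr_model`: list with `descriptors`, `coef` (intercept
#'   first), `se` (standard errors), `n_train`, `s` (residual standard
#'   deviation), `df_residual`.
#' @examples
#' X <- cbind(x1 = 1:10, x2 = (1:10)^2)
#' fit_mlr(X, 2 + 3 * X[, 1] - X[, 2])$coef
#' @export
fit_mlr <- function(X, y, names = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(names)) {
    names <- if (ncol(X) > 0L) paste0("x", seq_len(ncol(X))) else character(0)
  }
  if (ncol(X) > 0L) colnames(X) <- names
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("need more training rows than coefficients")
  core <- .ols_core(X, y)
  if (is.null(core)) {
    stop("singular design matrix; collinear columns among: ",
         paste(names, collapse = ", "))
  }
  df <- n - p - 1L
  s2 <- sum(core$resid^2) / df
  XtXinv <- chol2inv(qr.R(core$qr))
  se <- sqrt(diag(XtXinv) * s2)
  structure(list(
    descriptors = names,
    coef = core$beta,
    se = setNames(se, names(core$beta)),
    n_train = n,
    s = sqrt(s2),
    df_residual = df
  ), class = "mlr_model")
}

#' Predict from an MLR model
#'
#' @param object an `mlr_model`.
#' @param newdata matrix or data.frame containing (at least) the model's
#'   descriptor columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata)[, , drop = FALSE])
  if (length(object$descriptors) == 0L) {
    return(rep(unname(object$coef[1L]), nrow(newdata)))
  }
  miss <- setdiff(object$descriptors, colnames(newdata))
  if (length(miss)) {
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  }
  X <- newdata[, object$descriptors, drop = FALSE]
  storage.mode(X) <- "double"
  drop(object$coef[1L] + X %*% object$coef[-1L])
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("<mlr_model> ", length(x$descriptors), " descriptors, n_train = ",
      x$n_train, "\n", sep = "")
  print(round(cbind(coef = x$coef, se = x$se), 4))
  invisible(x)
}

#' The published six-descriptor factor Xa model
#'
#' The frozen multilinear model for factor Xa inhibition (pKi as a function
#' of six topological/charge descriptors), with coefficients and their
#' standard errors exactly as published, fitted on 897 training molecules:
#'
#' \deqn{pKi = 6.176 + 1.513\,ringCplus\_sumpc + 0.519\,aroN\_sp2C\_4B +
#'   1.197\,fClamdN5B - 1.018\,fsp2Osp3O6B - 1.091\,fsp2Nsp3O9B -
#'   0.9\,fsp2Csp2O8B}
#'
#' @return an `mlr_model` usable with [predict.mlr_model()].
#' @examples
#' m <- published_model()
#' predict(m, data.frame(ringCplus_sumpc = 0, aroN_sp2C_4B = 0,
#'   fClamdN5B = 0, fsp2Osp3O6B = 0, fsp2Nsp3O9B = 0, fsp2Csp2O8B = 0))
#' @export
published_model <- function() {
  nm <- c("ringCplus_sumpc", "aroN_sp2C_4B", "fClamdN5B",
          "fsp2Osp3O6B", "fsp2Nsp3O9B", "fsp2Csp2O8B")
  coefs <- c(`(Intercept)` = 6.176, ringCplus_sumpc = 1.513,
             aroN_sp2C_4B = 0.519, fClamdN5B = 1.197,
             fsp2Osp3O6B = -1.018, fsp2Nsp3O9B = -1.091,
             fsp2Csp2O8B = -0.9)
  se <- c(`(Intercept)` = 0.073, ringCplus_sumpc = 0.104,
          aroN_sp2C_4B = 0.04, fClamdN5B = 0.077,
          fsp2Osp3O6B = 0.099, fsp2Nsp3O9B = 0.111,
          fsp2Csp2O8B = 0.158)
  structure(list(descriptors = nm, coef = coefs, se = se,
                 n_train = 897L, s = 0.478, df_residual = 897L - 6L - 1L),
            class = "mlr_model")
}

#' Goodness-of-fit statistics
#'
#' `r2` is the coefficient of determination `1 - SSres/SStot`; `rmse` and
#' `mae` are root-mean-square and mean absolute errors; `ccc` is Lin's
#' concordance correlation coefficient computed with population (1/n)
#' moments: `2 cov(y, yhat) / (var(y) + var(yhat) + (mean(y) - mean(yhat))^2)`.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return a single numeric value.
#' @export
r2 <- function(y, yhat) {
  .check_pair(y, yhat)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("undefined statistic: zero variance in y")
  1 - sum((y - yhat)^2) / sst
}

#' @rdname r2
#' @export
rmse <- function(y, yhat) {
  .check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname r2
#' @export
mae <- function(y, yhat) {
  .check_pair(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname r2
#' @export
ccc <- function(y, yhat) {
  .check_pair(y, yhat)
  n <- length(y)
  my <- mean(y); mp <- mean(yhat)
  vy <- mean((y - my)^2); vp <- mean((yhat - mp)^2)
  if (vy == 0 && vp == 0 && my == mp) return(1)
  if (vy == 0) stop("undefined statistic: zero variance in y")
  cv <- mean((y - my) * (yhat - mp))
  2 * cv / (vy + vp + (my - mp)^2)
}

.check_pair <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L,
            all(is.finite(y)), all(is.finite(yhat)))
}
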
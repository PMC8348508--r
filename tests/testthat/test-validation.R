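test_that("PRESS-based leave-one-out equals the explicit refit loop", {
  set.seed(31)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(30, sd = 0.4)
  loo <- q2_loo(X, y)
  refit <- vapply(seq_len(30), function(i) {
    m <- fit_mlr(X[-i, , drop = FALSE], y[-i])
    unname(predict(m, X[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(loo$pred, refit, tolerance = 1e-10)
  expect_equal(loo$q2, 1 - sum((y - refit)^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
})

test_that("perfect linear data give Q2 of one", {
  set.seed(32)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 1 + drop(X %*% c(1, -2, 0.5, 3))
  expect_equal(q2_loo(X, y)$q2, 1, tolerance = 1e-8)
  expect_equal(q2_lmo(X, y, leave_fraction = 0.25, iterations = 50, seed = 1),
               1, tolerance = 1e-8)
})

test_that("cross-validated Q2 never exceeds the training R2", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(25:60, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    m <- fit_mlr(X, y)
    r2tr <- r2(y, predict(m, X))
    expect_lte(q2_loo(X, y)$q2, r2tr + 1e-12)
  }
})

test_that("leave-many-out reduces to leave-one-out under exhaustive singleton groups", {
  set.seed(34)
  X <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1] + rnorm(12, sd = 0.3)
  expect_equal(q2_lmo(X, y, groups = as.list(seq_len(12))),
               q2_loo(X, y)$q2, tolerance = 1e-12)
})

test_that("leave-many-out is seed-reproducible", {
  set.seed(35)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 2] + rnorm(50, sd = 0.5)
  a <- q2_lmo(X, y, iterations = 30, seed = 9)
  b <- q2_lmo(X, y, iterations = 30, seed = 9)
  expect_identical(a, b)
})

test_that("external statistics hit their defining values for perfect predictions", {
  set.seed(36)
  X <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, paste0("x", 1:4)))
  beta <- c(0.5, 1, -1, 2, 0.3)
  y_tr <- rnorm(40, mean = 5)
  y_ext <- beta[1] + drop(X %*% beta[-1]) + 5
  model <- structure(list(descriptors = colnames(X),
                          coef = c(`(Intercept)` = beta[1] + 5,
                                   setNames(beta[-1], colnames(X))),
                          se = rep(0, 5), n_train = 40, s = 0.1,
                          df_residual = 35), class = "mlr_model")
  ext <- external_stats(model, X, y_ext, y_tr)
  expect_equal(ext$q2_f1, 1); expect_equal(ext$q2_f2, 1)
  expect_equal(ext$q2_f3, 1); expect_equal(ext$ccc_ex, 1)
  expect_equal(ext$k, 1); expect_equal(ext$kp, 1)
  expect_equal(ext$ro2, 1); expect_equal(ext$rpo2, 1)
  expect_equal(ext$r2m, 1)
})

test_that("a constant prediction bias is visible in the external block", {
  set.seed(37)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y_ext <- 5 + drop(X %*% c(1, -1, 0.5, 2))
  model <- structure(list(descriptors = colnames(X),
                          coef = c(`(Intercept)` = 5 + 1.5,
                                   setNames(c(1, -1, 0.5, 2), colnames(X))),
                          se = rep(0, 5), n_train = 40, s = 0.1,
                          df_residual = 35), class = "mlr_model")
  ext <- external_stats(model, X, y_ext, rnorm(40, mean = 5))
  expect_lt(ext$q2_f2, 1)
  expect_false(isTRUE(all.equal(ext$k, 1)))
  expect_equal(ext$r2_ex, 1)   # shift leaves the correlation intact
})

test_that("external statistics match direct formula evaluation", {
  set.seed(38)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y_tr <- rnorm(50, mean = 6, sd = 1.2)
  y_ext <- rnorm(20, mean = 6, sd = 1.2)
  model <- fit_mlr(matrix(rnorm(200), 50, 4,
                          dimnames = list(NULL, colnames(X))), y_tr)
  ext <- external_stats(model, X, y_ext, y_tr)
  yhat <- predict(model, X)
  sse <- sum((y_ext - yhat)^2)
  expect_equal(ext$q2_f1, 1 - sse / sum((y_ext - mean(y_tr))^2))
  expect_equal(ext$q2_f2, 1 - sse / sum((y_ext - mean(y_ext))^2))
  expect_equal(ext$q2_f3,
               1 - (sse / 20) / (sum((y_tr - mean(y_tr))^2) / 50))
  expect_equal(ext$k, sum(y_ext * yhat) / sum(yhat^2))
  expect_equal(ext$kp, sum(y_ext * yhat) / sum(y_ext^2))
})

test_that("Y-scrambling destroys a strong model and excludes the identity", {
  pt <- gen_planted_table(n = 120, p_decoy = 0, sigma = 0, seed = 39)
  ysc <- y_scramble(pt$X, pt$y, n_iter = 100, seed = 7)
  # unscrambled fit is exact; identity permutation would score R2 = 1
  expect_true(all(ysc$table$r2 < 0.999))
  expect_lt(ysc$r2_mean, 0.2)
  ysc2 <- y_scramble(pt$X, pt$y, n_iter = 100, seed = 7)
  expect_identical(ysc$table, ysc2$table)
})

test_that("leverages satisfy the hat-matrix identities and h* formula", {
  expect_equal(round(3 * (6 + 1) / 897, 3), 0.023)
  set.seed(40)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(paste0("m", 1:50),
                                                 paste0("x", 1:4)))
  y <- X[, 1] + rnorm(50, sd = 0.5)
  model <- fit_mlr(X, y)
  ad <- williams_ad(model, X, y)
  tr <- ad$table[ad$table$set == "train", ]
  expect_equal(sum(tr$leverage), 4 + 1, tolerance = 1e-10)
  expect_true(all(tr$leverage >= 0 & tr$leverage <= 1))
  expect_equal(ad$h_star, 3 * 5 / 50)

  # intercept-only model: every training leverage is 1/n
  m0 <- fit_mlr(matrix(numeric(0), 50, 0), y)
  ad0 <- williams_ad(m0, matrix(numeric(0), 50, 0), y)
  expect_equal(ad0$table$leverage, rep(1 / 50, 50), tolerance = 1e-12)
})

test_that("the validation report carries every statistic block", {
  set.seed(41)
  X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 + X[, 1] - X[, 2] + rnorm(60, sd = 0.4)
  rep_ <- validate_model(X[1:45, ], y[1:45], X[46:60, ], y[46:60],
                         names = paste0("x", 1:3), lmo_iterations = 50,
                         yscr_iterations = 100, seed = 4)
  expect_s3_class(rep_, "validation_report")
  expect_true(all(c("R2_tr", "R2_adj", "RMSE_tr", "MAE_tr", "s", "F",
                    "CCC_tr", "Kxy") %in% names(rep_$training)))
  expect_true(all(c("Q2_LOO", "RMSE_cv", "CCC_cv", "Q2_LMO") %in%
                    names(rep_$cv)))
  expect_true(all(c("q2_f1", "q2_f2", "q2_f3", "ccc_ex", "k", "kp",
                    "ro2", "rpo2", "r2m") %in% names(rep_$external)))
  expect_lte(rep_$cv$Q2_LOO, rep_$training$R2_tr)
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep_, path)
  js <- jsonlite::fromJSON(path)
  expect_true(all(c("R2_tr", "Q2_LOO", "Q2_LMO", "CCC_tr", "Q2_F1",
                    "Q2_F2", "Q2_F3", "R2_Yscr", "h_star") %in% names(js)))
  expect_equal(js$R2_tr, rep_$training$R2_tr)
})
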
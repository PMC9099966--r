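test_that("a single latent variable fits rank-1 data exactly", {
  z <- withr::with_seed(1, rnorm(30))
  X <- outer(z, c(1, 2, -1, 0.5))
  y <- 3 * z
  m <- fit_pls(X, y, n_lv = 1)
  expect_lt(max(abs(m$fitted - y)), 1e-10)
})

test_that("model invariants hold on random problems", {
  for (seed in 1:4) {
    dat <- latent_regression(seed = seed)
    m <- fit_pls(dat$X, dat$y, n_lv = 4)
    G <- crossprod(m$T)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
    expect_lt(max(abs(colSums(m$W^2) - 1)), 1e-12)
    # declared decompositions: X = T P' + E with E the deflation residual,
    # and the residual is orthogonal to the scores
    expect_lt(max(abs(crossprod(m$T, sweep(dat$X, 2, m$x_center) -
                                       tcrossprod(m$T, m$P)))),
              1e-6)
  }
})

test_that("fitted values are invariant to scaling X by a constant", {
  dat <- latent_regression(seed = 5)
  m1 <- fit_pls(dat$X, dat$y, n_lv = 3)
  m2 <- fit_pls(dat$X * 37.5, dat$y, n_lv = 3)
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-9)
})

test_that("PLS at full column rank matches the least-squares oracle", {
  X <- withr::with_seed(6, matrix(rnorm(40 * 5), 40, 5))
  y <- withr::with_seed(7, as.numeric(X %*% c(1, -2, 0.5, 0, 3) +
                                        rnorm(40, 0, 0.1)))
  m <- fit_pls(X, y, n_lv = 5)
  ols <- lm.fit(cbind(1, X), y)
  expect_lt(max(abs(m$fitted - cbind(1, X) %*% ols$coefficients)), 1e-6)
})

test_that("prediction identities hold", {
  dat <- latent_regression(seed = 8)
  m <- fit_pls(dat$X, dat$y, n_lv = 3)
  expect_equal(predict(m, dat$X), m$fitted)
  # the mean training spectrum predicts the training mean response
  expect_equal(drop(predict(m, matrix(colMeans(dat$X), 1))),
               mean(dat$y), tolerance = 1e-10)
  # duplicated rows give duplicated predictions
  two <- dat$X[c(4, 4), ]
  pr <- predict(m, two)
  expect_identical(pr[1, ], pr[2, ])
  expect_error(predict(m, dat$X[, 1:10]), "channel count")
})

test_that("rank exhaustion truncates with a warning", {
  z <- withr::with_seed(9, rnorm(20))
  X <- outer(z, c(1, -1, 2)) # rank 1
  expect_warning(m <- fit_pls(X, z + rnorm(20, 0, 0.01), n_lv = 3),
                 "truncated")
  expect_lt(m$n_lv, 3L)
})

test_that("pure-noise responses do not break fitting", {
  X <- withr::with_seed(10, matrix(rnorm(40 * 20), 40, 20))
  y <- withr::with_seed(11, rnorm(40))
  m <- fit_pls(X[1:20, ], y[1:20], n_lv = 1)
  r2_holdout <- r_squared(y[21:40], drop(predict(m, X[21:40, ])))
  expect_lt(abs(r2_holdout), 1)  # finite, no explosive extrapolation
})

test_that("cross-validation selects the planted component count", {
  # X is almost exactly rank 2 and y is linear in the two factors with
  # small noise, so the data are fit by 2 LVs and further components can
  # only chase cross-validation noise
  hits <- 0L
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      Z <- matrix(rnorm(80 * 2), 80, 2)
      A <- matrix(rnorm(2 * 20), 2, 20)
      list(X = Z %*% A + matrix(rnorm(80 * 20, 0, 1e-3), 80),
           y = as.numeric(Z %*% c(1.2, -0.8) + rnorm(80, 0, 0.05)))
    })
    cv <- select_lv(dat$X, dat$y, max_lv = 6, folds = 5, seed = seed)
    hits <- hits + (cv$n_lv == 2L)
  }
  expect_gte(hits, 9L)
})

test_that("cross-validation is deterministic and respects bounds", {
  dat <- latent_regression(seed = 12)
  cv1 <- select_lv(dat$X, dat$y, max_lv = 5, folds = 5, seed = 3)
  cv2 <- select_lv(dat$X, dat$y, max_lv = 5, folds = 5, seed = 3)
  expect_identical(cv1[c("rmsecv", "r2cv", "n_lv", "fold")],
                   cv2[c("rmsecv", "r2cv", "n_lv", "fold")])
  cv_one <- select_lv(dat$X, dat$y, max_lv = 1, folds = 5, seed = 3)
  expect_equal(cv_one$n_lv, 1L)
  expect_error(select_lv(dat$X[1:5, ], dat$y[1:5], folds = 5, seed = 1),
               "fewer than 2")
})

test_that("out-of-fold predictions never depend on a sample's own response", {
  dat <- latent_regression(seed = 13)
  cv <- select_lv(dat$X, dat$y, max_lv = 3, folds = 4, seed = 2,
                  keep_pred = TRUE)
  f1 <- which(cv$fold == 1L)
  y_mod <- dat$y
  y_mod[f1] <- y_mod[f1] + 100  # corrupt fold-1 responses
  cv_mod <- select_lv(dat$X, y_mod, max_lv = 3, folds = 4, seed = 2,
                      keep_pred = TRUE)
  # fold-1 predictions come from models trained without fold 1
  expect_equal(cv$cv_pred[f1, , ], cv_mod$cv_pred[f1, , ])
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  dat <- latent_regression(n = 50, seed = 14)
  colnames(dat$X) <- paste0("ch", seq_len(ncol(dat$X)))
  m <- fit_pls(dat$X, dat$y, n_lv = 3)
  ref <- mixOmics::pls(dat$X, dat$y, ncomp = 3, scale = FALSE,
                       mode = "regression")
  pref <- predict(ref, dat$X)$predict[, 1, 3]
  expect_equal(drop(m$fitted), unname(pref), tolerance = 1e-6)
})

test_that("models survive a JSON round-trip", {
  dat <- latent_regression(seed = 15)
  m <- fit_pls(dat$X, dat$y, n_lv = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, path)
  back <- read_pls_model(path)
  expect_equal(predict(back, dat$X), predict(m, dat$X), tolerance = 1e-10)
  expect_equal(back$n_lv, m$n_lv)
})
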
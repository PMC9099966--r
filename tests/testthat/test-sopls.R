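test_that("a2 = 0 reproduces plain PLS on the first block exactly", {
  dat <- two_block_data(seed = 1)
  s <- fit_sopls(dat$X1, dat$X2, dat$y, a1 = 3, a2 = 0)
  m <- fit_pls(dat$X1, dat$y, n_lv = 3)
  expect_equal(s$fitted, m$fitted)
  expect_equal(predict(s, dat$X1, dat$X2), predict(m, dat$X1))
})

test_that("orthogonalized block is orthogonal to stage-1 scores", {
  for (seed in 1:3) {
    dat <- two_block_data(seed = seed)
    s <- fit_sopls(dat$X1, dat$X2, dat$y, a1 = 2, a2 = 2)
    scale <- max(abs(s$T1)) * max(abs(dat$X2))
    expect_lt(max(abs(crossprod(s$T1, s$X2orth))), 1e-8 * scale)
  }
})

test_that("a duplicated block contributes nothing at full stage-1 rank", {
  z <- withr::with_seed(4, matrix(rnorm(40 * 2), 40, 2))
  X1 <- z %*% matrix(rnorm(2 * 15), 2, 15)  # rank 2
  y <- withr::with_seed(5, as.numeric(z %*% c(1, -1) + rnorm(40, 0, 0.01)))
  s <- suppressWarnings(fit_sopls(X1, X1, y, a1 = 2, a2 = 1))
  expect_lt(max(abs(s$X2orth)), 1e-6 * max(abs(X1)))
  pr <- predict(s, X1, X1, components = TRUE)
  expect_lt(max(abs(pr$stage2)), 1e-6 * max(abs(pr$total)))
})

test_that("predictions are invariant to rescaling either block", {
  dat <- two_block_data(seed = 6)
  base <- predict(fit_sopls(dat$X1, dat$X2, dat$y, 2, 2), dat$X1, dat$X2)
  s1 <- fit_sopls(dat$X1 * 1000, dat$X2, dat$y, 2, 2)
  expect_equal(predict(s1, dat$X1 * 1000, dat$X2), base, tolerance = 1e-8)
  s2 <- fit_sopls(dat$X1, dat$X2 * 1000, dat$y, 2, 2)
  expect_equal(predict(s2, dat$X1, dat$X2 * 1000), base, tolerance = 1e-8)
})

test_that("stage predictions add up to the total exactly", {
  dat <- two_block_data(seed = 7)
  s <- fit_sopls(dat$X1, dat$X2, dat$y, 2, 2)
  new1 <- dat$X1[1:10, ]; new2 <- dat$X2[1:10, ]
  pr <- predict(s, new1, new2, components = TRUE)
  expect_identical(pr$total, pr$stage1 + pr$stage2)
  # training inputs reproduce the training fitted values
  expect_equal(predict(s, dat$X1, dat$X2), s$fitted)
  # single-sample prediction equals the matching batch row
  one <- predict(s, dat$X1[3, , drop = FALSE], dat$X2[3, , drop = FALSE])
  expect_equal(drop(one), drop(predict(s, dat$X1, dat$X2)[3, ]))
})

test_that("new X2 lying in the stage-1 score image yields no stage-2 signal", {
  dat <- two_block_data(seed = 8)
  s <- fit_sopls(dat$X1, dat$X2, dat$y, 2, 2)
  # construct X2_new whose centered values are exactly T1_new %*% G
  t1_new <- pls_scores(s$block1_model, dat$X1[1:8, ])
  X2_new <- sweep(t1_new %*% s$G, 2, s$x2_center, `+`)
  pr <- predict(s, dat$X1[1:8, ], X2_new, components = TRUE)
  # the stage-2 input is then exactly zero, so its contribution is the
  # stage-2 intercept only (the stage-1 residual mean, which is ~0)
  expect_lt(max(abs(pr$stage2)), 1e-8 * max(abs(pr$total)))
})

test_that("degenerate component requests are rejected", {
  dat <- two_block_data(seed = 9)
  expect_error(fit_sopls(dat$X1, dat$X2, dat$y, 0, 0), "empty model")
  expect_error(fit_sopls(dat$X1[1:10, ], dat$X2, dat$y, 1, 1),
               "same samples")
  s <- fit_sopls(dat$X1, dat$X2, dat$y, 1, 1)
  expect_error(predict(s, dat$X1, dat$X2[, 1:5]), "channel count")
})

test_that("a1 = 0 defers everything to the second block", {
  dat <- two_block_data(seed = 10, share2 = 1)
  s <- fit_sopls(dat$X1, dat$X2, dat$y, a1 = 0, a2 = 3)
  m <- fit_pls(dat$X2, dat$y, n_lv = 3)
  expect_equal(predict(s, dat$X1, dat$X2), predict(m, dat$X2),
               tolerance = 1e-10)
})

test_that("the CV grid finds where the information lives", {
  # y driven by block 1 only -> a2 = 0 selected in most replicates
  a2_zero <- 0L
  for (seed in 1:10) {
    dat <- two_block_data(share2 = 0, y_noise = 0.05, seed = seed)
    g <- sopls_select_lv(dat$X1, dat$X2, dat$y, max_a1 = 3, max_a2 = 3,
                         folds = 5, seed = seed)
    a2_zero <- a2_zero + (g$a2 == 0L)
  }
  expect_gte(a2_zero, 8L)
  # complementary blocks -> a2 >= 1 selected in most replicates
  a2_pos <- 0L
  for (seed in 1:10) {
    dat <- two_block_data(share2 = 0.5, y_noise = 0.05, seed = seed)
    g <- sopls_select_lv(dat$X1, dat$X2, dat$y, max_a1 = 3, max_a2 = 3,
                         folds = 5, seed = seed)
    a2_pos <- a2_pos + (g$a2 >= 1L)
  }
  expect_gte(a2_pos, 8L)
})

test_that("grid selection is deterministic under a fixed seed", {
  dat <- two_block_data(seed = 11)
  g1 <- sopls_select_lv(dat$X1, dat$X2, dat$y, 3, 3, folds = 5, seed = 4)
  g2 <- sopls_select_lv(dat$X1, dat$X2, dat$y, 3, 3, folds = 5, seed = 4)
  expect_identical(g1[c("a1", "a2", "rmsecv", "fold")],
                   g2[c("a1", "a2", "rmsecv", "fold")])
})

test_that("fold models never see their own test responses", {
  dat <- two_block_data(seed = 12)
  g <- sopls_select_lv(dat$X1, dat$X2, dat$y, 2, 2, folds = 4, seed = 5,
                       keep_pred = TRUE)
  f1 <- which(g$fold == 1L)
  y_mod <- dat$y
  y_mod[f1] <- y_mod[f1] - 50
  g_mod <- sopls_select_lv(dat$X1, dat$X2, y_mod, 2, 2, folds = 4,
                           seed = 5, keep_pred = TRUE)
  expect_equal(g$cv_pred[f1, , ], g_mod$cv_pred[f1, , ])
})

test_that("sequential fusion of complementary blocks beats block 1 alone", {
  wins <- 0L
  for (seed in 1:10) {
    dat <- two_block_data(n = 80, share2 = 0.5, y_noise = 0.05,
                          seed = seed + 100)
    tr <- 1:60; te <- 61:80
    cv1 <- select_lv(dat$X1[tr, ], dat$y[tr], max_lv = 4, folds = 5,
                     seed = seed)
    m1 <- fit_pls(dat$X1[tr, ], dat$y[tr], cv1$n_lv)
    g <- sopls_select_lv(dat$X1[tr, ], dat$X2[tr, ], dat$y[tr], 4, 4,
                         folds = 5, seed = seed)
    s <- fit_sopls(dat$X1[tr, ], dat$X2[tr, ], dat$y[tr], g$a1, g$a2)
    rmse_pls <- rmse(dat$y[te], drop(predict(m1, dat$X1[te, ])))
    rmse_so <- rmse(dat$y[te], drop(predict(s, dat$X1[te, ],
                                            dat$X2[te, ])))
    wins <- wins + (rmse_so <= rmse_pls)
  }
  expect_gte(wins, 9L)
})
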
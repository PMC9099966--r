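test_that("moving average follows the shrinking-window edge rule", {
  expect_equal(moving_average(c(2, 2, 2, 2, 2, 2), 5), rep(2, 6))
  x <- c(1, 2, 3, 4, 5, 6, 7)
  out <- moving_average(x, 5)
  expect_equal(out[3], 3)               # full centered window
  expect_equal(out[1], mean(1:3))       # shrunk to available neighbors
  expect_equal(out[2], mean(1:4))
  expect_equal(moving_average(x, 1), x) # identity window
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 9), "exceeds")
})

test_that("max normalization scales to unity and is idempotent", {
  expect_equal(max_normalize(c(2, 4, 8)), c(0.25, 0.5, 1))
  d <- small_dataset(seed = 1)
  nrm <- max_normalize(d$mir)
  expect_equal(unname(apply(nrm$values, 1, max)), rep(1, n_samples(nrm)))
  expect_equal(max_normalize(nrm)$values, nrm$values, tolerance = 1e-12)
  expect_error(max_normalize(c(0, 0, 0)), "non-positive")
})

test_that("SNV standardizes each spectrum and is affine-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  d <- small_dataset(seed = 2)
  s <- snv(d$mir)
  expect_lt(max(abs(rowMeans(s$values))), 1e-12)
  expect_lt(max(abs(apply(s$values, 1, sd) - 1)), 1e-12)
  # affine distortion a + b*x (b > 0) leaves the SNV output unchanged
  x <- d$mir$values[1, ]
  expect_equal(snv(3.2 + 1.7 * x), snv(x), tolerance = 1e-10)
  # exact idempotence
  expect_equal(snv(s)$values, s$values, tolerance = 1e-12)
  expect_error(snv(rep(5, 10)), "constant")
})

test_that("MSC inverts affine scatter against the reference", {
  ref <- sin(seq(0, 3, length.out = 40)) + 2
  # spectrum equal to the reference is unchanged
  expect_equal(drop(msc(matrix(ref, 1), reference = ref)), ref,
               ignore_attr = TRUE)
  # affine distortion 3 + 2*ref is mapped back to the reference
  expect_equal(drop(msc(matrix(3 + 2 * ref, 1), reference = ref)), ref,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(msc(matrix(ref, 1), reference = rep(1, 40)), "non-constant")
})

test_that("Savitzky-Golay reproduces low-order polynomials and smooths noise", {
  idx <- seq_len(41)
  quad <- 0.02 * idx^2 - 0.3 * idx + 4
  out <- savitzky_golay(quad, window = 11, polyorder = 2)
  interior <- 6:36
  expect_equal(out[interior], quad[interior], tolerance = 1e-9)
  noisy <- withr::with_seed(3, sin(idx / 4) + rnorm(41, 0, 0.3))
  expect_lte(var(savitzky_golay(noisy, 11, 2)), var(noisy))
  expect_error(savitzky_golay(rnorm(5), window = 11), "exceeds")
  expect_error(savitzky_golay(quad, window = 10), "odd")
  expect_error(savitzky_golay(quad, window = 3, polyorder = 3), "exceed")
})

test_that("ALS baseline removes ramps but preserves peaks", {
  p <- 400L
  ramp <- seq(0, 10, length.out = p)
  out <- baseline_correct(matrix(ramp, 1))
  expect_lt(max(abs(out)), 0.05)  # ramp-only input flattened to ~0
  peak <- 6 * exp(-((seq_len(p) - 200)^2) / (2 * 8^2))
  rec <- baseline_correct(matrix(ramp + peak, 1))
  expect_lt(abs(max(rec) - 6) / 6, 0.05)  # peak height within 5%
  expect_equal(drop(baseline_correct(matrix(0, 1, p))), rep(0, p),
               ignore_attr = TRUE)
  expect_error(baseline_correct(matrix(c(1, NA, 3), 1)), "non-finite")
})

test_that("Compton normalization fixes the window integral at one", {
  d <- small_dataset(seed = 4, n_xrf_channels = 300L)
  win <- c(18, 22)
  cn <- compton_normalize(d$xrf, win)
  ax <- cn$axis
  idx <- which(ax >= win[1] & ax <= win[2])
  integ <- apply(cn$values[, idx], 1, function(v) {
    sum(diff(ax[idx]) * (v[-1] + v[-length(v)]) / 2)
  })
  expect_equal(unname(integ), rep(1, n_samples(cn)), tolerance = 1e-12)
  # scale invariance and idempotence
  scaled <- spectra_block(d$xrf$values * 10, d$xrf$axis, d$xrf$samples)
  expect_equal(compton_normalize(scaled, win)$values, cn$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(compton_normalize(cn, win)$values, cn$values,
               tolerance = 1e-12)
  expect_error(compton_normalize(d$xrf, c(40, 50)), "outside axis range")
})

test_that("channel dropping excises the detector-spike interval", {
  d <- small_dataset(seed = 5, n_xrf_channels = 200L)
  cut <- drop_channels(d$xrf, c(2.3, 2.7))
  expect_true(all(cut$axis < 2.3 | cut$axis > 2.7))
  expect_equal(n_samples(cut), n_samples(d$xrf))
  expect_error(drop_channels(d$xrf, c(-1, 40)), "every channel")
})

test_that("every operator preserves sample count and order", {
  d <- small_dataset(seed = 6, n_xrf_channels = 150L)
  ops <- list(function(b) moving_average(b, 5),
              max_normalize, snv, msc,
              function(b) savitzky_golay(b, 11, 2),
              baseline_correct,
              function(b) compton_normalize(b, c(18, 22)))
  for (op in ops) {
    out <- op(d$xrf)
    expect_identical(out$samples, d$xrf$samples)
    expect_equal(n_samples(out), n_samples(d$xrf))
  }
})

test_that("recipes apply operators in order and presets match the roster", {
  d <- small_dataset(seed = 7)
  # MIR preset for pH: moving average then normalization -> max is 1
  out <- apply_recipe(d$mir, recipe_preset("MIR", "pH"))
  expect_equal(unname(apply(out$values, 1, max)), rep(1, n_samples(out)))
  ops_of <- function(s) vapply(s$steps, `[[`, "", "op")
  expect_equal(ops_of(recipe_preset("MIR", "K")), "moving_average")
  expect_equal(ops_of(recipe_preset("MIR", "P")),
               c("moving_average", "snv"))
  expect_equal(tail(ops_of(recipe_preset("XRF", "Ca")), 1), "msc")
  expect_equal(ops_of(recipe_preset("XRF", "pH")),
               c("baseline_correct", "compton_normalize",
                 "moving_average", "max_normalize"))
  # empty step list is the identity
  ident <- apply_recipe(d$mir, preprocess_spec(list(), "MIR"))
  expect_identical(ident$values, d$mir$values)
  expect_error(preprocess_spec(list(list(op = "wavelets")), "MIR"),
               "unknown operator")
})

test_that("fitted recipes freeze training statistics for test data", {
  d <- small_dataset(seed = 8, n_samples = 30L)
  tr <- 1:20; te <- 21:30
  block_tr <- subset_channels(d$mir, TRUE)  # copy
  block_tr$values <- block_tr$values[tr, ]; block_tr$samples <- d$mir$samples[tr]
  block_te <- subset_channels(d$mir, TRUE)
  block_te$values <- block_te$values[te, ]; block_te$samples <- d$mir$samples[te]
  spec <- preprocess_spec(list(list(op = "moving_average", window = 5L),
                               list(op = "msc")), "MIR")
  fitted <- fit_recipe(spec, block_tr)
  # the frozen reference is the training mean after the preceding step
  ref <- fitted$steps[[2]]$reference
  expect_equal(ref, colMeans(moving_average(block_tr)$values),
               ignore_attr = TRUE)
  # applying the fitted recipe to test data uses the training reference,
  # not the test mean
  out_te <- apply_recipe(block_te, fitted)
  manual <- msc(moving_average(block_te), reference = ref)
  expect_equal(out_te$values, manual$values)
  expect_false(isTRUE(all.equal(out_te$values,
                                apply_recipe(block_te, spec)$values)))
})

test_that("recipes serialize to JSON and back", {
  spec <- recipe_preset("XRF", "P")
  path <- withr::local_tempfile(fileext = ".json")
  write_recipe(spec, path)
  back <- read_recipe(path)
  expect_equal(vapply(back$steps, `[[`, "", "op"),
               vapply(spec$steps, `[[`, "", "op"))
  expect_equal(back$sensor, "XRF")
})
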
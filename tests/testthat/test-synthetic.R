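test_that("generation is a deterministic function of the config", {
  d1 <- small_dataset(seed = 7)
  d2 <- small_dataset(seed = 7)
  expect_identical(d1$mir$values, d2$mir$values)
  expect_identical(d1$xrf$values, d2$xrf$values)
  expect_identical(d1$attributes$values, d2$attributes$values)
  d3 <- small_dataset(seed = 8)
  expect_false(identical(d1$mir$values, d3$mir$values))
})

test_that("dataset dimensions and alignment match the configuration", {
  d <- small_dataset(seed = 2, n_samples = 25L, n_mir_channels = 70L,
                     n_xrf_channels = 90L)
  expect_equal(dim(d$mir$values), c(25L, 70L))
  expect_equal(dim(d$xrf$values), c(25L, 90L))
  expect_identical(d$mir$samples, d$xrf$samples)
  expect_identical(d$mir$samples, d$attributes$samples)
  expect_equal(nrow(d$latents), 25L)
  # MIR axis descending in wavenumber, XRF ascending in energy
  expect_true(all(diff(d$mir$axis) < 0))
  expect_true(all(diff(d$xrf$axis) > 0))
})

test_that("both spectra families are nonnegative before preprocessing", {
  for (s in 1:3) {
    d <- small_dataset(seed = s)
    expect_gte(min(d$mir$values), 0)
    expect_gte(min(d$xrf$values), 0)
  }
})

test_that("noise-free construction is exactly linear with latent-spanned rank", {
  cfg <- small_config(seed = 5, noise_sd = 0, scatter_sd = 0,
                      complementarity = 0, mir_background = 0,
                      attr_snr = Inf, n_latents = 3L)
  d <- generate_soil_data(cfg)
  # rank of the noiseless MIR block equals the latent count
  sv <- svd(d$mir$values)$d
  expect_equal(sum(sv > 1e-9 * sv[1]), 3L)
  # attributes are exact affine functions of the MIR-group latents alone
  L1 <- d$latents[, 1:3]
  for (a in colnames(d$attributes$values)) {
    fit <- lm.fit(cbind(1, L1), d$attributes$values[, a])
    expect_lt(max(abs(fit$residuals)), 1e-9)
  }
})

test_that("complementarity monotonically shifts attribute information to XRF", {
  r2_mir <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cc) {
    d <- generate_soil_data(small_config(seed = 31, complementarity = cc,
                                         attr_snr = Inf, n_latents = 3L))
    L1 <- d$latents[, 1:3]
    mean(vapply(colnames(d$attributes$values), function(a) {
      y <- d$attributes$values[, a]
      suppressWarnings(summary(stats::lm(y ~ L1))$r.squared)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r2_mir) < 0))
  expect_gt(r2_mir[1], 0.999)   # all signal from MIR latents at c = 0
  expect_lt(r2_mir[5], 0.05)    # none at c = 1
})

test_that("attribute_ranges summarizes and handles degenerate inputs", {
  d <- small_dataset(seed = 3)
  rng <- attribute_ranges(d)
  expect_setequal(rng$attribute, c("pH", "OC", "P", "K", "Mg", "Ca", "MC"))
  expect_true(all(rng$min <= rng$mean & rng$mean <= rng$max))
  expect_true(all(rng$sd >= 0))
  # default-scale pH stays in a plausible soil envelope
  ph <- rng[rng$attribute == "pH", ]
  expect_gt(ph$mean, 6.5); expect_lt(ph$mean, 8.8)
  expect_gt(ph$min, 5.5);  expect_lt(ph$max, 10)
  # constant column and single-sample conventions
  tab <- attribute_table(cbind(pH = rep(4.2, 5)))
  r1 <- attribute_ranges(tab)
  expect_equal(r1$min, 4.2); expect_equal(r1$max, 4.2)
  expect_equal(r1$mean, 4.2); expect_equal(r1$sd, 0)
  one <- attribute_table(cbind(pH = 6.1))
  expect_equal(attribute_ranges(one)$sd, 0)  # documented single-sample rule
  expect_error(attribute_ranges(attribute_table(matrix(numeric(0), 0, 1,
                                                       dimnames = list(NULL, "pH")))),
               "empty")
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(synth_config(n_samples = 1), "n_samples")
  expect_error(synth_config(complementarity = 1.2), "complementarity")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(xrf_range = c(30, 0)), "xrf_range")
  expect_error(generate_soil_data(list()), "synth_config")
})
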
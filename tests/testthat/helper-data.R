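# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite carries no data files.

small_config <- function(seed = 1L, ...) {
  args <- list(n_samples = 40L, n_mir_channels = 60L, n_xrf_channels = 80L,
               n_latents = 2L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

small_dataset <- function(seed = 1L, ...) {
  generate_soil_data(small_config(seed = seed, ...))
}

# Latent-factor regression benchmark: X has a handful of informative
# channels driven by k factors plus pure-noise channels, y is linear in
# the factors. Used for PLS / VIP structure-recovery tests.
latent_regression <- function(n = 60L, p_info = 10L, p_noise = 40L,
                              k = 3L, noise = 0.05, y_noise = 0.05,
                              seed = 1L) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * k), n, k)
    A <- matrix(runif(k * p_info, 0.5, 1.5) * sample(c(-1, 1),
                                                    k * p_info,
                                                    replace = TRUE),
                k, p_info)
    X <- cbind(Z %*% A + matrix(rnorm(n * p_info, 0, noise), n),
               matrix(rnorm(n * p_noise), n))
    b <- runif(k, 0.5, 1.5)
    y <- as.numeric(Z %*% b + rnorm(n, 0, y_noise))
    list(X = X, y = y, Z = Z, p_info = p_info)
  })
}

# Paired two-block regression with a controllable information split,
# built directly (not via the soil generator) for SOPLS-specific tests.
two_block_data <- function(n = 60L, p1 = 30L, p2 = 40L, k1 = 2L, k2 = 2L,
                           share2 = 0.5, noise = 0.02, y_noise = 0.05,
                           seed = 1L) {
  withr::with_seed(seed, {
    Z1 <- matrix(rnorm(n * k1), n, k1)
    Z2 <- matrix(rnorm(n * k2), n, k2)
    A1 <- matrix(rnorm(k1 * p1), k1, p1)
    A2 <- matrix(rnorm(k2 * p2), k2, p2)
    X1 <- Z1 %*% A1 + matrix(rnorm(n * p1, 0, noise), n)
    X2 <- Z2 %*% A2 + matrix(rnorm(n * p2, 0, noise), n)
    y <- as.numeric(sqrt(1 - share2) * rowMeans(Z1) * sqrt(k1) +
                      sqrt(share2) * rowMeans(Z2) * sqrt(k2) +
                      rnorm(n, 0, y_noise))
    list(X1 = X1, X2 = X2, y = y, Z1 = Z1, Z2 = Z2)
  })
}
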
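# Shared helpers: independent numerical oracles and small cached fixtures.

# Independent PPK oracle: Simpson product-rule quadrature of the product of
# the two explicit Gaussian-mixture densities. Entirely separate from the
# closed-form implementation it checks.
quad_ppk <- function(a, b, p, n = 801) {
  mz_all <- c(a$peaks$mz, b$peaks$mz)
  I_all <- c(a$peaks$intensity, b$peaks$intensity)
  gx <- seq(min(mz_all) - 8 * p$sigma_mz, max(mz_all) + 8 * p$sigma_mz,
            length.out = n)
  gy <- seq(min(I_all) - 8 * p$sigma_int, max(I_all) + 8 * p$sigma_int,
            length.out = n)
  mixmat <- function(s) {
    dx <- sapply(s$peaks$mz, function(m) dnorm(gx, m, p$sigma_mz))
    dy <- sapply(s$peaks$intensity, function(m) dnorm(gy, m, p$sigma_int))
    (dx %*% t(dy)) / nrow(s$peaks)
  }
  Z <- mixmat(a) * mixmat(b)
  wx <- c(1, rep(c(4, 2), length.out = n - 3), 4, 1) * (gx[2] - gx[1]) / 3
  wy <- c(1, rep(c(4, 2), length.out = n - 3), 4, 1) * (gy[2] - gy[1]) / 3
  as.numeric(t(wx) %*% Z %*% wy)
}

rand_spectrum <- function(n_peaks = 5, mz_range = c(60, 300), max_int = 100) {
  ei_spectrum(sort(runif(n_peaks, mz_range[1], mz_range[2])),
              runif(n_peaks, 1, max_int))
}

# A small benchmark bundle shared across workflow tests (built lazily once).
.test_cache <- new.env(parent = emptyenv())
small_bundle <- function() {
  if (is.null(.test_cache$bundle)) {
    cfg <- generator_config(n_train = 60, n_test = 15, n_decoy_pool = 120,
                            candidates_per_query = 20, n_replicates = 0,
                            master_seed = 5)
    .test_cache$bundle <- make_benchmark(cfg)
  }
  .test_cache$bundle
}
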
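# Fixtures and independent oracles shared across test files.

# small synthetic spectra object with arbitrary positive reflectance on the
# full instrument grid (not vegetation-shaped; for algebraic tests)
random_spectra <- function(n = 5L, seed = 1L) {
  set.seed(seed)
  wl <- 350:1830
  refl <- matrix(runif(length(wl) * n, 0.05, 0.95), length(wl), n,
                 dimnames = list(NULL, sprintf("X%02d", seq_len(n))))
  spectra(wl, refl)
}

# naive per-pair double-loop correlation surface: the brute-force oracle for
# the blockwise search
brute_force_surface <- function(sp, target, formula_id, grid) {
  gi <- match(grid, sp$wavelength)
  R <- t(sp$reflectance[gi, , drop = FALSE])
  r550 <- refl_at(sp, 550L); r455 <- refl_at(sp, 455L)
  m <- length(grid)
  surf <- matrix(NA_real_, m, m, dimnames = list(grid, grid))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      v <- dual_band_value(formula_id, R[, i], R[, j], r550, r455)
      if (all(is.finite(v)) && stats::sd(v) > 0) surf[i, j] <- stats::cor(v, target)
    }
  }
  if (formula_id %in% c("RI", "DI", "NDVI", "VI6", "mSR", "mNDI")) diag(surf) <- NA_real_
  surf
}

# direct least-squares polynomial fit at one interior point: oracle for the
# Savitzky-Golay filter value
sg_point_oracle <- function(y, center, window, order) {
  h <- (window - 1L) %/% 2L
  idx <- (center - h):(center + h)
  fit <- lm(y[idx] ~ poly(seq(-h, h), order, raw = TRUE))
  unname(predict(fit)[h + 1L])
}

# a vegetation-shaped zero-noise experiment reused by several files
zero_noise_experiment <- function(seed = 42L) {
  cfg <- generator_config(seed = seed, plot_noise_sd = 0, spectral_noise_sd = 0,
                          layer_noise_sd = c(LL = 0, RL = 0))
  simulate_experiment(cfg)
}
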
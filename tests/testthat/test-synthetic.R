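test_that("design table is the complete factorial, deterministically", {
  cfg <- generator_config(seed = 5)
  d <- make_design(cfg)
  expect_equal(nrow(d), 48L)
  expect_equal(anyDuplicated(d[, c("year", "n_level", "inoculated", "replicate")]), 0L)
  expect_equal(sum(d$n_level == "N3" & d$inoculated), 6L)  # 2 years x 3 reps
  expect_identical(d, make_design(cfg))
  # every cell appears exactly once
  expect_true(all(table(d$year, d$n_level, d$inoculated) == 3L))
})

test_that("generator_config rejects invalid worlds", {
  expect_error(generator_config(plot_noise_sd = -1), "must be >= 0")
  expect_error(generator_config(layer_offsets = c(LL = -0.1, RL = 0.2)), "positive")
  bad <- default_treatment_means(); bad["N3", "plain"] <- 3.0
  expect_error(generator_config(treatment_means = bad), "increase with nitrogen")
  bad2 <- default_treatment_means(); bad2["N1", "inoculated"] <- 4.0
  expect_error(generator_config(treatment_means = bad2), "inoculated")
  expect_error(generator_config(layer_offsets = c(LL = 0.1, RL = 5)), "negative")
})

test_that("per-layer LNC: ordering, inoculation effect, determinism", {
  cfg0 <- generator_config(seed = 2, plot_noise_sd = 0, layer_noise_sd = c(LL = 0, RL = 0))
  d <- make_design(cfg0)
  l0 <- sample_lnc(d, cfg0)
  expect_equal(nrow(l0), 144L)
  w <- matrix(l0$lnc, ncol = 3, byrow = TRUE,
              dimnames = list(NULL, levels(l0$layer)[as.integer(l0$layer[1:3])]))
  # with zero noise the vertical gradient is forced for every sample
  by_layer <- split(l0$lnc, l0$layer)
  expect_true(all(tapply(l0$lnc, list(l0$sample_id, l0$layer), mean)[, "RL"] <
                  tapply(l0$lnc, list(l0$sample_id, l0$layer), mean)[, "LL"]))
  expect_true(all(tapply(l0$lnc, list(l0$sample_id, l0$layer), mean)[, "LL"] <
                  tapply(l0$lnc, list(l0$sample_id, l0$layer), mean)[, "CL"]))
  # inoculation raises the canopy mean at fixed N level (defaults encode RN3 > N3)
  cl <- l0[l0$layer == "CL", ]
  m <- tapply(cl$lnc, list(cl$n_level, cl$inoculated), mean)
  expect_true(all(m[, "TRUE"] > m[, "FALSE"]))
  # monotone in nitrogen level at fixed inoculation
  expect_true(all(diff(m[, "FALSE"]) > 0) && all(diff(m[, "TRUE"]) > 0))
  # seeded bit-for-bit reproducibility with noise on
  cfg <- generator_config(seed = 9)
  expect_identical(sample_lnc(d, cfg), sample_lnc(d, cfg))
})

test_that("layer ordering survives default noise for >= 95% of samples over 100 seeds", {
  frac <- vapply(1:100, function(s) {
    cfg <- generator_config(seed = s)
    l <- sample_lnc(make_design(cfg), cfg)
    m <- tapply(l$lnc, list(l$sample_id, l$layer), mean)
    mean(m[, "RL"] < m[, "LL"] & m[, "LL"] < m[, "CL"])
  }, numeric(1))
  expect_gte(mean(frac), 0.95)
})

test_that("generated spectra are plausible, bounded and coupled to nitrogen", {
  cfg <- generator_config(seed = 1, spectral_noise_sd = 0)
  wl <- 350:1830
  for (lnc in c(3.1, 4.5, 5.7)) {
    r <- generate_spectrum(lnc, cfg)
    expect_length(r, 1481L)
    expect_true(all(r > 0 & r < 1))
    # local maximum (green peak) inside 510-560 nm
    win <- which(wl >= 500 & wl <= 570)
    peak <- win[which.max(r[win])]
    expect_true(wl[peak] >= 510 && wl[peak] <= 560)
    # NIR plateau above red valley
    expect_gt(mean(r[wl >= 760 & wl <= 900]), mean(r[wl >= 650 & wl <= 690]))
  }
  # deeper chlorophyll well at 670 nm for higher nitrogen
  r_lo <- generate_spectrum(3.2, cfg); r_hi <- generate_spectrum(5.6, cfg)
  expect_lt(r_hi[wl == 670], r_lo[wl == 670])
  # determinism at zero spectral noise
  expect_identical(generate_spectrum(4.2, cfg, 7L), generate_spectrum(4.2, cfg, 7L))
  expect_error(generate_spectrum(-1, cfg), "> 0")
  # a coupling that overshoots the physical range is rejected
  bad <- cfg; bad$coupling$red_edge <- c(1.2, 0)
  expect_error(generate_spectrum(4.5, bad), "outside")
})

test_that("simulate_experiment aligns spectra with the design", {
  ex <- simulate_experiment(generator_config(seed = 4))
  expect_equal(sample_ids(ex$spectra), ex$design$sample_id)
  expect_equal(nrow(ex$lnc), 144L)
  ex2 <- simulate_experiment(generator_config(seed = 4))
  expect_identical(ex$spectra$reflectance, ex2$spectra$reflectance)
})

test_that("plant_signal plants an exactly recoverable linear signal", {
  ex <- zero_noise_experiment()
  sm <- sg_smooth(ex$spectra)
  pl <- plant_signal(sm, ex$lnc, c(700, 800), "VI6", slope = 2, noise_sd = 0)
  idx <- dual_band_value("VI6", refl_at(sm, 700), refl_at(sm, 800))
  y <- layer_target(pl, "CL", sample_ids(sm))
  expect_equal(unname(cor(y, idx)), 1, tolerance = 1e-12)
  expect_identical(attr(pl, "planted_pair"), c(700L, 800L))
  # noiseless search attains |r| = 1 somewhere
  surf <- correlation_surface(sm, y, "VI6", stride = 25)
  expect_equal(abs(surf$best$r), 1, tolerance = 1e-9)
  # degenerate planted index is rejected
  const <- spectra(350:1830, matrix(0.4, 1481, 5))
  expect_error(plant_signal(const, ex$lnc[1:15, ], c(700, 800), "DI"), "degenerate")
})
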
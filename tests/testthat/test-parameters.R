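# hand-evaluated single-point oracle for each closed-form formula
make_point_spectrum <- function(values) {
  wl <- 350:1830
  r <- rep(0.4, length(wl))
  for (nm in names(values)) r[wl == as.integer(nm)] <- values[[nm]]
  spectra(wl, matrix(r, ncol = 1, dimnames = list(NULL, "pt")))
}

test_that("empirical indices match hand evaluations", {
  sp <- make_point_spectrum(list(`800` = 0.5, `670` = 0.05, `1510` = 0.1, `1680` = 0.2,
                                 `749` = 0.5, `720` = 0.4, `701` = 0.2, `672` = 0.15,
                                 `680` = 0.1, `678` = 0.3, `500` = 0.2, `550` = 0.25,
                                 `833` = 0.45, `658` = 0.09, `1100` = 0.4, `600` = 0.12,
                                 `700` = 0.24))
  e <- empirical_indices(sp)[1, ]
  expect_equal(unname(e["OSAVI"]), 1.16 * 0.45 / 0.71, tolerance = 1e-6)
  expect_equal(unname(e["OSAVI"]), 0.7352, tolerance = 1e-4)
  expect_equal(unname(e["NDNI"]), 0.17718, tolerance = 1e-4)
  expect_equal(unname(e["DD"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(e["D800/680"]), 5, tolerance = 1e-12)
  expect_equal(unname(e["D678/500"]), 1.5, tolerance = 1e-12)
  expect_equal(unname(e["D833/658"]), 5, tolerance = 1e-12)
  expect_equal(unname(e["IPVI"]), 0.5 * 0.55, tolerance = 1e-12)          # printed product form
  expect_equal(unname(e["AVI"]), 2 * 0.5 / 0.4 - 0.12 / 0.24, tolerance = 1e-12)
  expect_equal(unname(e["DVI_MSS"]), 2.4 * 0.5 / 0.4 - 0.12 / 0.24, tolerance = 1e-12)
  # configuration switches select the alternative readings
  e2 <- empirical_indices(sp, ipvi_literature = TRUE, avi_product = TRUE)[1, ]
  expect_equal(unname(e2["IPVI"]), 0.5 / 0.55, tolerance = 1e-12)
  expect_equal(unname(e2["AVI"]), 2 * 0.5 * 0.4 - 0.12 * 0.24, tolerance = 1e-12)
})

test_that("NDNI is invariant to the logarithm base", {
  # algebraic identity: scaling both logs cancels in the ratio
  ndni <- function(base) {
    l <- function(x) log(1 / x, base = base)
    (l(0.1) - l(0.2)) / (l(0.1) + l(0.2))
  }
  expect_equal(ndni(exp(1)), ndni(10), tolerance = 1e-12)
  expect_equal(ndni(2), log(2) / log(50), tolerance = 1e-12)
})

test_that("dual-band formulas match hand evaluations and identities", {
  expect_equal(dual_band_value("VI6", 0.5, 0.25), -2)
  expect_equal(dual_band_value("TVI", 0.5, 0.2, r_550 = 0.1), 14)
  expect_equal(dual_band_value("mNDI", 0.5, 0.3, r_455 = 0.1), 1 / 3, tolerance = 1e-6)
  expect_equal(dual_band_value("SAVI", 0.5, 0.05), 1.16 * 0.45 / 0.71, tolerance = 1e-12)
  expect_equal(dual_band_value("mSR", 0.5, 0.3, r_455 = 0.1), 2)
  set.seed(3)
  ri <- runif(20, 0.05, 0.95); rj <- runif(20, 0.05, 0.95)
  r550 <- runif(20, 0.05, 0.95); r455 <- runif(20, 0.01, 0.04)
  # zero at i = j for the difference family
  for (f in c("DI", "NDVI", "VI6")) {
    expect_equal(dual_band_value(f, ri, ri), rep(0, 20))
    # antisymmetry under swap
    expect_equal(dual_band_value(f, ri, rj), -dual_band_value(f, rj, ri), tolerance = 1e-12)
  }
  # RI inverts, PI/SI symmetric
  expect_equal(dual_band_value("RI", ri, rj), 1 / dual_band_value("RI", rj, ri), tolerance = 1e-12)
  expect_equal(dual_band_value("PI", ri, rj), dual_band_value("PI", rj, ri))
  expect_equal(dual_band_value("SI", ri, rj), dual_band_value("SI", rj, ri))
  # normalized forms bounded for positive reflectance
  expect_true(all(abs(dual_band_value("NDVI", ri, rj)) <= 1))
  expect_true(all(abs(dual_band_value("mNDI", ri, rj, r_455 = r455)) <= 1))
  # singularities yield the NA sentinel
  expect_true(is.na(dual_band_value("RI", 0.5, 0)))
  expect_true(is.na(dual_band_value("VI6", 0, 0.5)))
  expect_true(is.na(dual_band_value("mSR", 0.5, 0.1, r_455 = 0.1)))
  expect_true(is.na(dual_band_value("mNDI", 0.3, 0.1, r_455 = 0.2)))
  expect_error(dual_band_value("XXX", 0.5, 0.2), "unknown")
  expect_error(dual_band_value("TVI", 0.5, 0.2), "requires r_550")
})

test_that("trilateral parameters: telescoping areas, window extrema, contrasts", {
  sp <- random_spectra(4, seed = 9)
  sm <- sg_smooth(sp)
  tri <- trilateral_parameters(sm)
  # areas telescope exactly to endpoint reflectance differences
  expect_equal(tri[, "S_b"], refl_at(sm, 530) - refl_at(sm, 490), tolerance = 1e-12)
  expect_equal(tri[, "S_y"], refl_at(sm, 642) - refl_at(sm, 462), tolerance = 1e-12)
  expect_equal(tri[, "S_r"], refl_at(sm, 760) - refl_at(sm, 670), tolerance = 1e-12)
  # monotone increasing spectrum: positive derivative maxima, R_g at the
  # right window edge, R_r at the left
  wl <- 350:1830
  mono <- spectra(wl, matrix(seq(0.1, 0.9, length.out = length(wl))^1.5, ncol = 1))
  tm <- trilateral_parameters(mono)
  expect_true(all(tm[, c("D_b", "D_y", "D_r")] > 0))
  expect_equal(unname(tm[, "R_g"]), unname(mono$reflectance[wl == 560, 1]))
  expect_equal(unname(tm[, "R_r"]), unname(mono$reflectance[wl == 650, 1]))
  # NDD_rb = 0 when D_r = D_b (symmetric triangle spectrum is overkill;
  # verify the algebra on the computed values instead)
  expect_equal(tri[, "NDD_rb"],
               (tri[, "D_r"] - tri[, "D_b"]) / (tri[, "D_r"] + tri[, "D_b"]),
               tolerance = 1e-12)
  expect_equal(tri[, "NDSD_rb"],
               (tri[, "S_r"] - tri[, "S_b"]) / (tri[, "S_r"] + tri[, "S_b"]),
               tolerance = 1e-12)
  # the printed yellow edge contains the blue edge, so D_y >= D_b always
  expect_true(all(tri[, "D_y"] >= tri[, "D_b"]))
})

test_that("parameter matrix has the documented 48 x 30 shape and determinism", {
  ex <- zero_noise_experiment()
  sm <- sg_smooth(ex$spectra)
  pairs <- setNames(lapply(dual_band_formulas(), function(f) c(700L, 800L)),
                    dual_band_formulas())
  pm <- parameter_matrix(sm, pairs)
  expect_equal(dim(pm), c(48L, 30L))
  expect_equal(as.vector(table(attr(pm, "param_class"))[c("dualband", "empirical", "trilateral")]),
               c(10L, 10L, 10L))
  expect_false(anyDuplicated(colnames(pm)) > 0)
  expect_true(all(attr(pm, "n_undefined") == 0))
  # determinism
  expect_identical(pm, parameter_matrix(sm, pairs))
  # permuting samples permutes rows only
  perm <- rev(seq_len(48))
  pm2 <- parameter_matrix(sm[perm], pairs)
  expect_equal(pm2[, ], pm[perm, ])
  # missing pair is rejected
  expect_error(parameter_matrix(sm, pairs[-1]), "missing wavelength pair")
})
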
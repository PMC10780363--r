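#' Registry of dual-band index formulas
#'
#' The ten two-free-wavelength index formulas searched exhaustively against
#' the nitrogen trait. `TVI` additionally uses the fixed band R_550, and
#' `mSR` / `mNDI` the fixed band R_455.
#'
#' @return character vector of formula identifiers.
#' @export
dual_band_formulas <- function() {
  c("RI", "DI", "SAVI", "NDVI", "TVI", "mSR", "mNDI", "PI", "SI", "VI6")
}

# formulas that are degenerate (constant or undefined) on the diagonal i = j
diagonal_degenerate <- function(formula_id) {
  formula_id %in% c("RI", "DI", "NDVI", "VI6", "mSR", "mNDI")
}

#' Evaluate a dual-band index formula
#'
#' Vectorized elementwise evaluation of one registry formula:
#' \describe{
#'   \item{RI}{`Ri / Rj`}
#'   \item{DI}{`Ri - Rj`}
#'   \item{SAVI}{`1.16 (Ri - Rj) / (Ri + Rj + 0.16)`}
#'   \item{NDVI}{`(Ri - Rj) / (Ri + Rj)`}
#'   \item{TVI}{`0.5 * (120 (Ri - R550) - 200 (Rj - R550))`}
#'   \item{mSR}{`(Ri - R455) / (Rj - R455)`}
#'   \item{mNDI}{`(Ri - Rj) / (Ri + Rj - 2 R455)`}
#'   \item{PI}{`Ri * Rj`}
#'   \item{SI}{`Ri + Rj`}
#'   \item{VI6}{`1/Ri - 1/Rj` (reciprocal difference)}
#' }
#' Singularities (division by zero) yield the undefined-value sentinel `NA`.
#'
#' @param formula_id one of [dual_band_formulas()].
#' @param r_i,r_j reflectance vectors at the two free wavelengths.
#' @param r_550,r_455 reflectance at the fixed auxiliary bands (only needed
#'   by TVI and mSR/mNDI respectively).
#' @return numeric vector of index values, `NA` where undefined.
#' @examples
#' dual_band_value("VI6", 0.5, 0.25) # -2
#' @export
dual_band_value <- function(formula_id, r_i, r_j, r_550 = NULL, r_455 = NULL) {
  v <- switch(formula_id,
    RI   = r_i / r_j,
    DI   = r_i - r_j,
    SAVI = 1.16 * (r_i - r_j) / (r_i + r_j + 0.16),
    NDVI = (r_i - r_j) / (r_i + r_j),
    TVI  = {
      if (is.null(r_550)) stop("TVI requires r_550")
      0.5 * (120 * (r_i - r_550) - 200 * (r_j - r_550))
    },
    mSR  = {
      if (is.null(r_455)) stop("mSR requires r_455")
      (r_i - r_455) / (r_j - r_455)
    },
    mNDI = {
      if (is.null(r_455)) stop("mNDI requires r_455")
      (r_i - r_j) / (r_i + r_j - 2 * r_455)
    },
    PI   = r_i * r_j,
    SI   = r_i + r_j,
    VI6  = 1 / r_i - 1 / r_j,
    stop(sprintf("unknown dual-band formula '%s'", formula_id))
  )
  v[!is.finite(v)] <- NA_real_
  v
}

#' Empirical nitrogen-sensitive spectral indices
#'
#' The ten fixed-wavelength indices of the empirical class, evaluated on a
#' (smoothed) full-grid spectrum set:
#' IPVI, OSAVI, NDNI, AVI, D678/500, D800/550, D800/680, D833/658, DVI_MSS
#' and DD. Two typeset ambiguities in the source formulary are resolved by
#' configuration switches (see the methods vignette): `IPVI` defaults to the
#' printed product form `R800 (R800 + R670)` (`ipvi_literature = TRUE` gives
#' the literature ratio `R800 / (R800 + R670)`), and `AVI` / `DVI_MSS`
#' default to the band-ratio reading `2 (R800/R1100) - (R600/R700)`
#' (`avi_product = TRUE` gives the literal product reading).
#'
#' @param x a `spectra` object on the full instrument grid.
#' @param ipvi_literature,avi_product formula-variant switches (see above).
#' @return numeric matrix samples x 10, `NA` sentinel where a ratio or log
#'   form is undefined.
#' @export
empirical_indices <- function(x, ipvi_literature = FALSE, avi_product = FALSE) {
  validate_spectra(x, full_grid = TRUE)
  at <- function(wl) refl_at(x, wl)
  R800 <- at(800); R670 <- at(670)
  ipvi <- if (ipvi_literature) R800 / (R800 + R670) else R800 * (R800 + R670)
  osavi <- 1.16 * (R800 - R670) / (R800 + R670 + 0.16)
  ndni <- (log(1 / at(1510)) - log(1 / at(1680))) /
          (log(1 / at(1510)) + log(1 / at(1680)))
  avi_core <- if (avi_product) {
    function(k) k * at(800) * at(1100) - at(600) * at(700)
  } else {
    function(k) k * (at(800) / at(1100)) - at(600) / at(700)
  }
  dd <- (at(749) - at(720)) - (at(701) - at(672))
  m <- cbind(IPVI = ipvi, OSAVI = osavi, NDNI = ndni, AVI = avi_core(2),
             `D678/500` = at(678) / at(500), `D800/550` = at(800) / at(550),
             `D800/680` = at(800) / at(680), `D833/658` = at(833) / at(658),
             DVI_MSS = avi_core(2.4), DD = dd)
  m[!is.finite(m)] <- NA_real_
  rownames(m) <- sample_ids(x)
  m
}

# window extremum with ties broken toward the shorter wavelength
window_stat <- function(values, wl, a, b, fun = max) {
  sel <- wl >= a & wl <= b
  v <- values[sel, , drop = FALSE]
  apply(v, 2L, fun)
}

#' Three-edge ("trilateral") derivative parameters
#'
#' Features of the first-derivative spectrum in the blue (490--530 nm),
#' yellow (462--642 nm, as printed in the source formulary, overlapping the
#' blue edge) and red (670--760 nm) edge windows: the derivative maxima
#' `D_b, D_y, D_r`; the green-peak maximum reflectance `R_g` (510--560 nm)
#' and red-valley minimum `R_r` (650--690 nm); the edge areas `S_b, S_y,
#' S_r` (sums of derivative entries with `a <= lambda < b`, which telescope
#' exactly to `R(b) - R(a)`); and the normalized contrasts
#' `NDD_rb = (D_r - D_b)/(D_r + D_b)` and `NDSD_rb = (S_r - S_b)/(S_r +
#' S_b)`.
#'
#' @param x a (smoothed) `spectra` object on the full grid.
#' @param deriv the matching [first_derivative()] of `x`; computed if `NULL`.
#' @return numeric matrix samples x 10 with the columns above; the
#'   normalized forms are `NA` when their denominator is zero.
#' @export
trilateral_parameters <- function(x, deriv = NULL) {
  validate_spectra(x, full_grid = TRUE)
  if (is.null(deriv)) deriv <- first_derivative(x)
  dwl <- deriv$wavelength; d <- deriv$d_reflectance
  wl <- x$wavelength; r <- x$reflectance
  edge_sum <- function(a, b) colSums(d[dwl >= a & dwl < b, , drop = FALSE])
  D_b <- window_stat(d, dwl, 490, 530); D_y <- window_stat(d, dwl, 462, 642)
  D_r <- window_stat(d, dwl, 670, 760)
  R_g <- window_stat(r, wl, 510, 560); R_r <- window_stat(r, wl, 650, 690, min)
  S_b <- edge_sum(490, 530); S_y <- edge_sum(462, 642); S_r <- edge_sum(670, 760)
  ndd <- (D_r - D_b) / (D_r + D_b)
  ndsd <- (S_r - S_b) / (S_r + S_b)
  m <- cbind(D_b = D_b, D_y = D_y, D_r = D_r, R_g = R_g, R_r = R_r,
             S_b = S_b, S_y = S_y, S_r = S_r, NDD_rb = ndd, NDSD_rb = ndsd)
  m[!is.finite(m)] <- NA_real_
  rownames(m) <- sample_ids(x)
  m
}

#' Assemble the full parameter matrix
#'
#' One row per sample, 30 named columns: the 10 empirical indices, the 10
#' trilateral parameters, and the 10 dual-band formulas evaluated at the
#' supplied wavelength pairs (normally the per-layer optima from the pair
#' search). Column classes are recorded in the `"param_class"` attribute and
#' undefined sentinels are counted per column in `"n_undefined"`.
#'
#' @param x a (smoothed) `spectra` object on the full grid.
#' @param pairs named list mapping every [dual_band_formulas()] id to an
#'   integer wavelength pair `c(i, j)`.
#' @param deriv optional precomputed [first_derivative()] of `x`.
#' @param ... passed to [empirical_indices()].
#' @return numeric matrix samples x 30 with attributes `param_class` (named
#'   character: empirical / trilateral / dualband) and `n_undefined`.
#' @export
parameter_matrix <- function(x, pairs, deriv = NULL, ...) {
  ids <- dual_band_formulas()
  if (!all(ids %in% names(pairs))) {
    stop(sprintf("missing wavelength pair for formula '%s'",
                 setdiff(ids, names(pairs))[1]))
  }
  emp <- empirical_indices(x, ...)
  tri <- trilateral_parameters(x, deriv)
  r550 <- refl_at(x, 550L); r455 <- refl_at(x, 455L)
  db <- vapply(ids, function(f) {
    p <- pairs[[f]]
    dual_band_value(f, refl_at(x, p[1]), refl_at(x, p[2]), r550, r455)
  }, numeric(n_samples(x)))
  m <- cbind(emp, tri, db)
  attr(m, "param_class") <- stats::setNames(
    rep(c("empirical", "trilateral", "dualband"), each = 10L), colnames(m))
  attr(m, "n_undefined") <- colSums(is.na(m))
  attr(m, "pairs") <- pairs
  m
}
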
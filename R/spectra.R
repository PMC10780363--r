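#' Hyperspectral reflectance container
#'
#' A `spectra` object stores one reflectance vector per sample on a shared,
#' strictly increasing 1 nm wavelength grid. The instrument convention
#' emulated throughout the package is a field spectroradiometer covering
#' 350--1830 nm interpolated to a 1 nm output grid (1481 bands).
#'
#' @param wavelength integer vector of wavelengths in nm, strictly increasing.
#' @param reflectance numeric matrix, one row per wavelength, one column per
#'   sample; values must lie in `[0, 1]` with no missing entries.
#' @param sample_ids optional character vector of sample identifiers; defaults
#'   to the column names of `reflectance`.
#'
#' @return An object of class `spectra`: a list with elements `wavelength`
#'   (integer) and `reflectance` (matrix with sample ids as column names).
#' @examples
#' wl <- 350:1830
#' refl <- matrix(0.3, length(wl), 2, dimnames = list(NULL, c("a", "b")))
#' sp <- spectra(wl, refl)
#' sp
#' @export
spectra <- function(wavelength, reflectance, sample_ids = colnames(reflectance)) {
  wavelength <- as.integer(wavelength)
  if (is.vector(reflectance)) reflectance <- matrix(reflectance, ncol = 1L)
  reflectance <- as.matrix(reflectance)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(reflectance)))
  colnames(reflectance) <- sample_ids
  obj <- structure(list(wavelength = wavelength, reflectance = reflectance),
                   class = "spectra")
  validate_spectra(obj)
  obj
}

#' Validate a spectra object
#'
#' Checks the invariants of the container: strictly increasing wavelength
#' grid, matching dimensions, unique sample ids, finite reflectance in
#' `[0, 1]`.
#'
#' @param x a `spectra` object.
#' @param full_grid if `TRUE`, additionally require the canonical instrument
#'   grid 350--1830 nm at a 1 nm step.
#' @return `x`, invisibly; errors describe the offending row or column.
#' @export
validate_spectra <- function(x, full_grid = FALSE) {
  if (!inherits(x, "spectra")) stop("not a 'spectra' object")
  wl <- x$wavelength
  if (anyNA(wl)) stop("wavelength grid contains missing values")
  dw <- diff(wl)
  if (any(dw <= 0)) {
    stop(sprintf("wavelength grid not strictly increasing at %d nm", wl[which(dw <= 0)[1] + 1L]))
  }
  if (full_grid) {
    expected <- 350:1830
    if (length(wl) != length(expected) || any(wl != expected)) {
      miss <- setdiff(expected, wl)
      if (length(miss)) stop(sprintf("wavelength grid has a gap at %d nm", miss[1]))
      stop("wavelength grid is not the 1 nm 350-1830 nm instrument grid")
    }
  }
  r <- x$reflectance
  if (nrow(r) != length(wl)) stop("reflectance rows do not match wavelength grid length")
  ids <- colnames(r)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop(sprintf("duplicate or missing sample id%s",
                 if (!is.null(ids)) sprintf(": '%s'", ids[anyDuplicated(ids)]) else ""))
  }
  if (anyNA(r) || any(!is.finite(r))) stop("reflectance contains missing or non-finite values")
  if (any(r < 0) || any(r > 1)) stop("reflectance outside [0, 1]")
  invisible(x)
}

#' @export
print.spectra <- function(x, ...) {
  wl <- x$wavelength
  cat(sprintf("<spectra> %d samples x %d bands (%d-%d nm)\n",
              ncol(x$reflectance), length(wl), min(wl), max(wl)))
  invisible(x)
}

#' @export
`[.spectra` <- function(x, i) {
  spectra(x$wavelength, x$reflectance[, i, drop = FALSE])
}

#' Number of samples in a spectra object
#' @param x a `spectra` object.
#' @return integer sample count.
#' @export
n_samples <- function(x) ncol(x$reflectance)

#' Sample identifiers of a spectra object
#' @param x a `spectra` object.
#' @return character vector of ids.
#' @export
sample_ids <- function(x) colnames(x$reflectance)

#' Reflectance at named wavelengths
#'
#' Extracts the reflectance row(s) for specific wavelengths (exact match on
#' the integer grid), as used by the fixed-band index formulas (R_445 ...
#' R_1680).
#'
#' @param x a `spectra` object.
#' @param wl integer wavelength(s) in nm.
#' @return numeric matrix `length(wl)` x samples (drop = FALSE semantics); a
#'   single wavelength returns a named numeric vector over samples.
#' @export
refl_at <- function(x, wl) {
  idx <- match(as.integer(wl), x$wavelength)
  if (anyNA(idx)) stop(sprintf("wavelength %d nm not on the grid", wl[which(is.na(idx))[1]]))
  out <- x$reflectance[idx, , drop = FALSE]
  if (length(wl) == 1L) out[1L, ] else out
}
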
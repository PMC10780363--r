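#' Savitzky-Golay convolution coefficients
#'
#' Central smoothing weights for a least-squares polynomial fit of the given
#' order in a symmetric moving window, i.e. the center row of the hat matrix
#' of the local polynomial regression.
#'
#' @param window odd integer window length (points).
#' @param order polynomial order, `< window`.
#' @return numeric vector of `window` convolution weights summing to 1.
#' @keywords internal
sg_coefficients <- function(window = 9L, order = 4L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L != 1L) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:order, `^`)
  # weight vector for the fitted value at the window center
  (A %*% solve(crossprod(A), t(A)))[h + 1L, ]
}

#' Savitzky-Golay smoothing of reflectance spectra
#'
#' Smooths every sample spectrum with a local least-squares polynomial filter.
#' The defaults follow the "9 points, order 4" convention of field
#' spectroscopy preprocessing. Edges are mirror-padded so the output grid
#' equals the input grid; all downstream parameter windows are interior, so
#' the edge policy cannot affect them.
#'
#' @param x a `spectra` object.
#' @param window odd window length in points (default 9).
#' @param order polynomial order (default 4); interior points reproduce any
#'   polynomial of degree `<= order` exactly.
#' @param passes number of repeated applications (default 1); exposed because
#'   the "4 times" phrasing of some protocols can also be read as iteration.
#' @return a `spectra` object on the same grid. Values are clipped to
#'   `[0, 1]` only if the filter overshoots the physical range.
#' @examples
#' sp <- spectra(350:1830, matrix(0.3, 1481, 1))
#' all.equal(sg_smooth(sp)$reflectance, sp$reflectance)
#' @export
sg_smooth <- function(x, window = 9L, order = 4L, passes = 1L) {
  validate_spectra(x)
  n <- length(x$wavelength)
  if (window >= n) stop("window must be shorter than the spectrum")
  w <- sg_coefficients(window, order)
  h <- (window - 1L) %/% 2L
  r <- x$reflectance
  for (p in seq_len(passes)) {
    # mirror padding about the end points (end point not duplicated)
    padded <- rbind(r[(h + 1L):2L, , drop = FALSE], r, r[(n - 1L):(n - h), , drop = FALSE])
    sm <- matrix(0, n, ncol(r))
    for (k in seq_len(window)) {
      sm <- sm + w[k] * padded[k:(k + n - 1L), , drop = FALSE]
    }
    r <- sm
  }
  r[r < 0] <- 0
  r[r > 1] <- 1
  spectra(x$wavelength, r, sample_ids(x))
}

#' First-derivative spectra
#'
#' Forward first difference of reflectance per nm, indexed at the left
#' endpoint: `d(lambda) = (R(lambda + 1) - R(lambda)) / 1 nm`. This
#' convention makes windowed derivative sums telescope exactly to endpoint
#' reflectance differences, the oracle used by the "edge area" parameters.
#'
#' @param x a `spectra` object on a 1 nm grid.
#' @return a `deriv_spectra` object: list with `wavelength` (left endpoints,
#'   one shorter than the source grid) and `d_reflectance` matrix.
#' @export
first_derivative <- function(x) {
  validate_spectra(x)
  if (any(diff(x$wavelength) != 1L)) stop("first_derivative expects a 1 nm grid")
  n <- length(x$wavelength)
  d <- x$reflectance[-1L, , drop = FALSE] - x$reflectance[-n, , drop = FALSE]
  structure(list(wavelength = x$wavelength[-n], d_reflectance = d),
            class = "deriv_spectra")
}

#' @export
print.deriv_spectra <- function(x, ...) {
  cat(sprintf("<deriv_spectra> %d samples x %d bands\n",
              ncol(x$d_reflectance), length(x$wavelength)))
  invisible(x)
}
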
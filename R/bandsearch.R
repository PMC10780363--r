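#' Pearson correlation with a two-sided p value
#'
#' Sample Pearson correlation between two vectors with pairwise deletion of
#' undefined sentinels (`NA`), and the two-sided p value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n` (pairs used). `r` and `p` are `NA` when
#'   fewer than 3 complete pairs remain or either side has zero variance.
#' @examples
#' pearson_r_with_p(1:10, (1:10) * -2)$r # -1
#' @export
pearson_r_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Critical correlation magnitude at a significance level
#'
#' The |r| boundary at which the two-sided Pearson test reaches `alpha` for
#' sample size `n`, from the closed-form t-quantile conversion
#' `r* = t* / sqrt(n - 2 + t*^2)`. At `n = 48`, `alpha = 0.05` this is
#' 0.2845, the screening gate used throughout.
#'
#' @param n sample size (>= 3).
#' @param alpha two-sided significance level.
#' @return positive scalar critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) stop("n must be >= 3")
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(n - 2 + tstar^2)
}

# correlation of each column of M with target t, pairwise-deleting NA;
# zero-variance columns give NA
col_cor <- function(M, t) {
  bad <- colSums(!is.finite(M)) > 0L
  r <- rep(NA_real_, ncol(M))
  if (any(!bad)) {
    Mo <- M[, !bad, drop = FALSE]
    tc <- t - mean(t)
    Mc <- sweep(Mo, 2L, colMeans(Mo))
    den <- sqrt(colSums(Mc^2)) * sqrt(sum(tc^2))
    ri <- colSums(Mc * tc) / den
    ri[den == 0] <- NA_real_
    r[!bad] <- ri
  }
  if (any(bad)) {
    for (k in which(bad)) r[k] <- pearson_r_with_p(M[, k], t)$r
  }
  r
}

#' Wavelength-pair correlation surface for one dual-band formula
#'
#' Evaluates the chosen formula at every ordered wavelength pair `(i, j)` of
#' the search grid, correlates the per-sample index values with the target
#' trait vector, and records the full signed-correlation surface together
#' with the optimal pair. Computation is blocked by `i` (one `samples x
#' bands` matrix at a time) so peak memory stays bounded on the full 1481
#' band grid.
#'
#' @param x a (smoothed) `spectra` object.
#' @param target numeric trait vector aligned with the samples of `x`.
#' @param formula_id one of [dual_band_formulas()].
#' @param grid integer wavelengths to search (subset of the instrument
#'   grid); defaults to the full grid. See also `stride`.
#' @param stride convenience: if given, the grid is every `stride`-th band
#'   starting at the first wavelength.
#' @return a `pair_search` object: list with `formula_id`, `grid`,
#'   `r_surface` (bands x bands signed Pearson matrix, rows = i, cols = j,
#'   `NA` where undefined or degenerate), `n`, and `best` = list(i, j, r, p).
#' @export
correlation_surface <- function(x, target, formula_id, grid = NULL, stride = NULL) {
  validate_spectra(x)
  if (length(target) != n_samples(x)) stop("target length must match sample count")
  if (!is.null(stride)) grid <- x$wavelength[seq(1L, length(x$wavelength), by = stride)]
  if (is.null(grid)) grid <- x$wavelength
  grid <- as.integer(grid)
  if (!all(grid %in% x$wavelength)) stop("search grid must be a subset of the instrument grid")
  gi <- match(grid, x$wavelength)
  R <- t(x$reflectance[gi, , drop = FALSE])      # samples x bands
  m <- length(grid)
  r550 <- refl_at(x, 550L); r455 <- refl_at(x, 455L)
  surf <- matrix(NA_real_, m, m, dimnames = list(grid, grid))
  for (ii in seq_len(m)) {
    M <- dual_band_value(formula_id, R[, ii], R, r550, r455)
    surf[ii, ] <- col_cor(M, target)
  }
  if (diagonal_degenerate(formula_id)) diag(surf) <- NA_real_
  if (all(!is.finite(surf))) stop("correlation surface is entirely undefined")
  res <- structure(list(formula_id = formula_id, grid = grid, r_surface = surf,
                        n = length(target)), class = "pair_search")
  res$best <- best_pair(res)
  res
}

#' @export
print.pair_search <- function(x, ...) {
  cat(sprintf("<pair_search> %s over %d bands; best |r| = %.3f at (%d, %d)\n",
              x$formula_id, length(x$grid), abs(x$best$r), x$best$i, x$best$j))
  invisible(x)
}

#' Optimal wavelength pair of a correlation surface
#'
#' The argmax of |r| over defined surface entries, ties broken toward the
#' smallest `i`, then the smallest `j`; returns the signed correlation.
#'
#' @param result a `pair_search` object (or a bare signed-correlation matrix
#'   with wavelength dimnames).
#' @return list with `i`, `j` (wavelengths, nm), `r` (signed), and `p`.
#' @export
best_pair <- function(result) {
  surf <- if (inherits(result, "pair_search")) result$r_surface else result
  n <- if (inherits(result, "pair_search")) result$n else NA_integer_
  a <- abs(surf)
  a[!is.finite(a)] <- -Inf
  best <- max(a)
  if (!is.finite(best)) stop("no defined entries in surface")
  hits <- which(a == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  i <- hits[1L, 1L]; j <- hits[1L, 2L]
  r <- surf[i, j]
  p <- if (is.na(n)) NA_real_ else {
    if (abs(r) >= 1) 0 else {
      t <- r * sqrt(n - 2) / sqrt(1 - r^2)
      2 * stats::pt(-abs(t), df = n - 2)
    }
  }
  list(i = as.integer(rownames(surf)[i]), j = as.integer(colnames(surf)[j]),
       r = r, p = p)
}

#' Optimal pairs of all dual-band formulas for one target
#'
#' Runs [correlation_surface()] for each formula and collects the optimum of
#' each, the computation behind a per-layer "best two-band index" table.
#'
#' @inheritParams correlation_surface
#' @param formulas formula ids to search (default: the full registry).
#' @param keep_surfaces if `TRUE`, the `pair_search` objects are attached as
#'   the `"surfaces"` attribute (memory: bands^2 doubles per formula).
#' @return data.frame with columns `formula, i, j, r, p, n`.
#' @export
optimize_pairs <- function(x, target, formulas = dual_band_formulas(),
                           grid = NULL, stride = NULL, keep_surfaces = FALSE) {
  res <- lapply(formulas, function(f) correlation_surface(x, target, f, grid, stride))
  out <- data.frame(formula = formulas,
                    i = vapply(res, function(z) z$best$i, integer(1)),
                    j = vapply(res, function(z) z$best$j, integer(1)),
                    r = vapply(res, function(z) z$best$r, numeric(1)),
                    p = vapply(res, function(z) z$best$p, numeric(1)),
                    n = vapply(res, function(z) z$n, integer(1)),
                    stringsAsFactors = FALSE)
  if (keep_surfaces) attr(out, "surfaces") <- stats::setNames(res, formulas)
  out
}
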
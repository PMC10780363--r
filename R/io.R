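#' Read spectra from wide CSV
#'
#' Expected schema: first column `wavelength_nm` (integer, strictly
#' increasing, the canonical grid is 350--1830 at 1 nm), one column per
#' sample. Schema violations are reported with the offending wavelength or
#' column.
#'
#' @param path CSV file path.
#' @param full_grid require the full instrument grid (default `TRUE`).
#' @return a [spectra()] object.
#' @export
read_spectra <- function(path, full_grid = TRUE) {
  if (!file.exists(path)) stop(sprintf("spectra file not found: '%s'", path))
  dt <- data.table::fread(path, data.table = FALSE)
  if (names(dt)[1] != "wavelength_nm") stop("first column must be 'wavelength_nm'")
  sp <- spectra(dt[[1]], as.matrix(dt[, -1, drop = FALSE]))
  validate_spectra(sp, full_grid = full_grid)
  sp
}

#' Write spectra to wide CSV
#' @param x a `spectra` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  validate_spectra(x)
  dt <- data.frame(wavelength_nm = x$wavelength, x$reflectance,
                   check.names = FALSE)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a tidy LNC table from CSV
#'
#' Schema: `sample_id, year, n_level, inoculated, replicate, layer, lnc`;
#' every sample must carry all three layers exactly once.
#'
#' @param path CSV file path.
#' @return data.frame with `layer` as an ordered-level factor `RL < LL < CL`.
#' @export
read_lnc <- function(path) {
  if (!file.exists(path)) stop(sprintf("LNC file not found: '%s'", path))
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("sample_id", "year", "n_level", "inoculated", "replicate", "layer", "lnc")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(sprintf("LNC file missing column '%s'", miss[1]))
  if (!all(d$layer %in% c("RL", "LL", "CL"))) {
    stop(sprintf("unknown layer code '%s'", setdiff(unique(d$layer), c("RL", "LL", "CL"))[1]))
  }
  tab <- table(d$sample_id, d$layer)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("sample '%s' does not have exactly one %s row",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]]))
  }
  d$layer <- factor(d$layer, levels = c("RL", "LL", "CL"))
  d$n_level <- factor(d$n_level, levels = c("N0", "N1", "N2", "N3"))
  d$inoculated <- as.logical(d$inoculated)
  d
}

#' Write a tidy LNC table to CSV
#' @param lnc tidy LNC data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lnc <- function(lnc, path) {
  data.table::fwrite(lnc, path)
  invisible(path)
}

#' Write the metrics table of an experiment grid
#' @param metrics data.frame from [run_experiment_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  data.table::fwrite(metrics, path)
  invisible(path)
}

#' Write a correlation surface to a (gzipped) CSV matrix
#'
#' Serializes the signed-correlation surface of a `pair_search` result as a
#' wavelength-by-wavelength CSV matrix (first column `i_nm`); a `.gz` suffix
#' compresses transparently.
#'
#' @param result a `pair_search` object.
#' @param path output path (e.g. `surface_VI6.csv.gz`).
#' @return `path`, invisibly.
#' @export
write_surface <- function(result, path) {
  d <- data.frame(i_nm = result$grid, result$r_surface, check.names = FALSE)
  data.table::fwrite(d, path, compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Render a correlation surface heatmap
#'
#' Writes one PNG heatmap of the signed correlation surface of a
#' `pair_search` result (derived artifact only, never an input).
#'
#' @param result a `pair_search` object.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(result, path) {
  grDevices::png(path, width = 900, height = 800)
  on.exit(grDevices::dev.off())
  surf <- result$r_surface
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(result$grid, result$grid, surf, col = pal,
                  zlim = c(-1, 1) * max(abs(surf), na.rm = TRUE),
                  xlab = "i wavelength (nm)", ylab = "j wavelength (nm)",
                  main = sprintf("%s: r(i, j); best (%d, %d), r = %.3f",
                                 result$formula_id, result$best$i,
                                 result$best$j, result$best$r))
  invisible(path)
}

#' Render an observed-vs-predicted scatter for one grid cell
#'
#' @param pred data.frame with `y`, `yhat`, `split` (one element of the
#'   `predictions` list of [run_experiment_grid()], or both splits bound
#'   together).
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
render_scatter <- function(pred, path, main = "") {
  grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  cols <- ifelse(pred$split == "modeling", "firebrick", "navy")
  lim <- range(c(pred$y, pred$yhat))
  graphics::plot(pred$y, pred$yhat, col = cols, pch = 19, xlim = lim, ylim = lim,
                 xlab = "observed LNC", ylab = "predicted LNC", main = main)
  graphics::abline(0, 1, lty = 2)
  invisible(path)
}
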
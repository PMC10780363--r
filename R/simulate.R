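#' Default canopy-layer treatment means
#'
#' Target mean canopy-leaf nitrogen concentration for each nitrogen rate
#' (N0--N3 = 0/60/120/180 kg ha^-1) with and without rhizobium seed
#' inoculation, on the dimensionless printed concentration scale (~3--6).
#' The defaults are the 2022 treatment means of the motivating field trial,
#' which increase monotonically with nitrogen rate and with inoculation at
#' every rate.
#'
#' @return numeric matrix, rows `N0..N3`, columns `plain` / `inoculated`.
#' @export
default_treatment_means <- function() {
  m <- rbind(N0 = c(3.13, 3.48),
             N1 = c(4.69, 4.97),
             N2 = c(5.13, 5.33),
             N3 = c(5.44, 5.70))
  colnames(m) <- c("plain", "inoculated")
  m
}

#' Configuration of the synthetic field experiment
#'
#' Bundles every tunable of the generator: the treatment means driving the
#' canopy-layer LNC, the vertical layer offsets and their plot-to-plot
#' jitter, the between-replicate noise, the reflectance noise, and the
#' coefficients coupling canopy LNC to the spectral features (chlorophyll
#' absorption wells, red-edge amplitude). See the methods vignette for how
#' each default was fixed.
#'
#' @param seed master integer seed; every random draw in the generator is a
#'   deterministic function of it.
#' @param treatment_means matrix as [default_treatment_means()]; must be
#'   strictly increasing down the rows (nitrogen rate) and from the plain to
#'   the inoculated column at every rate.
#' @param year_effect named additive shift per year applied to the canopy
#'   mean (default `+0.23` for 2021, the observed between-year difference).
#' @param layer_offsets positive mean drops from the canopy layer to the
#'   lateral (`LL`) and root (`RL`) layers.
#' @param layer_noise_sd sd of the per-sample layer drops: `LL` is the sd of
#'   the canopy-to-lateral drop, `RL` the sd of the additional
#'   lateral-to-root drop. Drops are lognormal, hence strictly positive:
#'   the vertical gradient `RL < LL < CL` holds for every sample while the
#'   lower layers decouple progressively from the canopy spectrum.
#' @param plot_noise_sd sd of the between-replicate canopy LNC variation.
#' @param spectral_noise_sd sd of additive reflectance noise per band.
#' @param coupling list of spectral shape coefficients; each `c(base, gain)`
#'   pair is evaluated as `base + gain * u` where
#'   `u = (lnc - 3) / 3` maps the printed LNC scale onto roughly `[0, 1]`.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             treatment_means = default_treatment_means(),
                             year_effect = c("2021" = 0.23, "2022" = 0),
                             layer_offsets = c(LL = 0.11, RL = 0.26),
                             layer_noise_sd = c(LL = 0.15, RL = 0.20),
                             plot_noise_sd = 0.15,
                             spectral_noise_sd = 0.005,
                             coupling = list(blue_well = c(0.035, 0.025),
                                             red_well = c(0.040, 0.030),
                                             red_edge = c(0.30, 0.12),
                                             green_peak = 0.06,
                                             baseline = 0.09,
                                             swir_drop = 0.10,
                                             water_dip = 0.16)) {
  if (plot_noise_sd < 0 || spectral_noise_sd < 0 || any(layer_noise_sd < 0)) {
    stop("noise standard deviations must be >= 0")
  }
  if (any(layer_offsets <= 0)) stop("layer offsets must be positive")
  if (any(diff(treatment_means[, "plain"]) <= 0) ||
      any(diff(treatment_means[, "inoculated"]) <= 0)) {
    stop("treatment means must increase with nitrogen level")
  }
  if (any(treatment_means[, "inoculated"] <= treatment_means[, "plain"])) {
    stop("inoculated means must exceed plain means at every nitrogen level")
  }
  if (any(treatment_means - max(layer_offsets) <= 0)) {
    stop("layer offsets would drive layer means negative")
  }
  structure(list(seed = as.integer(seed), treatment_means = treatment_means,
                 year_effect = year_effect, layer_offsets = layer_offsets,
                 layer_noise_sd = layer_noise_sd, plot_noise_sd = plot_noise_sd,
                 spectral_noise_sd = spectral_noise_sd, coupling = coupling),
            class = "generator_config")
}

# Evaluate a draw with a local RNG state so generator calls do not disturb
# (and are not disturbed by) the caller's random stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# lognormal draws parameterized by mean m and sd s (degenerate at s = 0)
rlnorm_ms <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  sdlog <- sqrt(log1p((s / m)^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

# fixed counter scheme: per-sample seeds derived from the master seed, kept
# inside the 32-bit integer range
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + counter * 16807) %% 2147483647)
}

#' Full-factorial experimental design
#'
#' The design of the emulated trial: 2 years x 4 nitrogen rates x 2 seed
#' dressing treatments x 3 replicates = 48 samples, completely crossed.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `sample_id`, `year`, `n_level`
#'   (factor N0..N3), `inoculated` (logical), `replicate`; exactly 48 rows.
#' @examples
#' nrow(make_design(generator_config()))
#' @export
make_design <- function(config = generator_config()) {
  d <- expand.grid(replicate = 1:3, inoculated = c(FALSE, TRUE),
                   n_level = c("N0", "N1", "N2", "N3"), year = c(2021L, 2022L),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("year", "n_level", "inoculated", "replicate")]
  d$n_level <- factor(d$n_level, levels = c("N0", "N1", "N2", "N3"))
  d <- data.frame(sample_id = sprintf("S%02d", seq_len(nrow(d))), d,
                  stringsAsFactors = FALSE)
  d
}

#' Draw per-layer leaf nitrogen concentrations
#'
#' Draws the canopy-layer LNC of each sample around its treatment-by-year
#' mean, then derives the lateral and root layers by subtracting positive
#' random drops (lognormal around the configured offsets), so the vertical
#' gradient `RL < LL < CL` holds for every sample while the magnitude of the
#' gradient varies plot to plot.
#'
#' @param design a design table from [make_design()].
#' @param config a [generator_config()].
#' @return tidy data.frame with one row per sample and layer (144 rows at the
#'   default design): `sample_id, year, n_level, inoculated, replicate,
#'   layer, lnc`, `layer` a factor with levels `RL < LL < CL`.
#' @export
sample_lnc <- function(design, config = generator_config()) {
  stopifnot(is.data.frame(design), all(c("sample_id", "year", "n_level", "inoculated") %in% names(design)))
  tm <- config$treatment_means
  mu <- tm[cbind(as.character(design$n_level),
                 ifelse(design$inoculated, "inoculated", "plain"))]
  mu <- mu + config$year_effect[as.character(design$year)]
  n <- nrow(design)
  extra_offset <- config$layer_offsets[["RL"]] - config$layer_offsets[["LL"]]
  if (extra_offset <= 0) stop("RL offset must exceed LL offset")
  draws <- with_seed(derive_seed(config$seed, 1L), {
    list(cl = stats::rnorm(n, 0, config$plot_noise_sd),
         drop_ll = rlnorm_ms(n, config$layer_offsets[["LL"]],
                             config$layer_noise_sd[["LL"]]),
         drop_rl = rlnorm_ms(n, extra_offset, config$layer_noise_sd[["RL"]]))
  })
  cl <- mu + draws$cl
  ll <- cl - draws$drop_ll
  rl <- ll - draws$drop_rl
  out <- data.frame(design[rep(seq_len(n), times = 3L), , drop = FALSE],
                    layer = factor(rep(c("CL", "LL", "RL"), each = n),
                                   levels = c("RL", "LL", "CL")),
                    lnc = pmax(c(cl, ll, rl), 1e-6),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(match(out$sample_id, design$sample_id), out$layer), , drop = FALSE]
}

# deterministic reflectance shape for a canopy LNC value, before noise
spectrum_shape <- function(lnc_cl, coupling, wl = 350:1830) {
  u <- (lnc_cl - 3) / 3
  cp <- coupling
  lin <- function(p) p[1] + p[2] * u
  cp$baseline +
    cp$green_peak * exp(-((wl - 550) / 35)^2) -
    lin(cp$blue_well) * exp(-((wl - 450) / 30)^2) -
    lin(cp$red_well) * exp(-((wl - 670) / 28)^2) +
    lin(cp$red_edge) * stats::plogis((wl - 718) / 12) -
    cp$swir_drop * stats::plogis((wl - 1350) / 80) -
    cp$water_dip * exp(-((wl - 1450) / 45)^2)
}

#' Generate one canopy reflectance spectrum
#'
#' Builds a mechanistic stand-in for a smoothed field canopy spectrum from
#' additive components: a flat visible baseline, chlorophyll absorption wells
#' near 450 and 670 nm whose depth grows with canopy LNC, a green reflectance
#' peak near 550 nm, a logistic red-edge rise (680--760 nm) whose amplitude
#' grows with LNC, a NIR plateau, a SWIR decline and a water absorption dip
#' near 1450 nm, plus additive Gaussian band noise.
#'
#' @param lnc_cl canopy-layer LNC (> 0) driving the shape.
#' @param config a [generator_config()]; `config$coupling` sets the component
#'   coefficients, `config$spectral_noise_sd` the band noise.
#' @param sample_seed integer seed for the noise draw of this sample.
#' @return numeric vector of 1481 reflectances on the 350--1830 nm grid, all
#'   in (0, 1).
#' @export
generate_spectrum <- function(lnc_cl, config = generator_config(), sample_seed = config$seed) {
  if (!is.finite(lnc_cl) || lnc_cl <= 0) stop("lnc_cl must be > 0")
  shape <- spectrum_shape(lnc_cl, config$coupling)
  if (any(shape <= 0) || any(shape >= 1)) {
    stop("coupling configuration produces reflectance outside (0, 1) before noise")
  }
  noise <- if (config$spectral_noise_sd > 0) {
    with_seed(sample_seed, stats::rnorm(length(shape), 0, config$spectral_noise_sd))
  } else 0
  pmin(pmax(shape + noise, 1e-6), 1 - 1e-6)
}

#' Simulate the full synthetic experiment
#'
#' Convenience wrapper: builds the design, draws per-layer LNC, and generates
#' one canopy spectrum per sample driven by that sample's canopy-layer LNC
#' (the instrument views the canopy; the lower layers are correlated targets
#' of the same spectrum).
#'
#' @param config a [generator_config()].
#' @return list with elements `design` (48-row data.frame), `lnc` (tidy
#'   144-row data.frame) and `spectra` (a [spectra()] object, one column per
#'   sample).
#' @examples
#' ex <- simulate_experiment(generator_config(seed = 7))
#' ex$spectra
#' @export
simulate_experiment <- function(config = generator_config()) {
  design <- make_design(config)
  lnc <- sample_lnc(design, config)
  cl <- lnc$lnc[lnc$layer == "CL"][match(design$sample_id, lnc$sample_id[lnc$layer == "CL"])]
  refl <- vapply(seq_len(nrow(design)), function(i) {
    generate_spectrum(cl[i], config, derive_seed(config$seed, 100L + i))
  }, numeric(1481L))
  list(design = design, lnc = lnc,
       spectra = spectra(350:1830, refl, design$sample_id))
}

#' Plant a known dual-band signal into the nitrogen table
#'
#' Replaces every LNC value by a linear function of a chosen dual-band index
#' evaluated at a fixed wavelength pair, plus independent noise per row. The
#' layer structure of the table is preserved. This provides exact ground
#' truth for wavelength-pair recovery tests of the correlation search.
#'
#' @param spectra a [spectra()] object.
#' @param lnc tidy LNC table aligned with `spectra` by `sample_id`.
#' @param pair integer `c(i, j)` wavelengths on the grid.
#' @param formula_id one of [dual_band_formulas()].
#' @param slope,intercept linear map from index value to planted LNC.
#' @param noise_sd sd of the additive noise; the default `NULL` uses 10% of
#'   the across-sample sd of the planted signal (the pilot-calibrated
#'   "default noise" of the recovery contract).
#' @param seed integer seed for the noise draws.
#' @return the LNC table with `lnc` replaced; attributes `planted_pair` and
#'   `planted_formula` record the ground truth.
#' @export
plant_signal <- function(spectra, lnc, pair, formula_id = "VI6",
                         slope = 1, intercept = 0, noise_sd = NULL, seed = 1L) {
  validate_spectra(spectra)
  idx <- dual_band_value(formula_id, refl_at(spectra, pair[1]), refl_at(spectra, pair[2]),
                         refl_at(spectra, 550L), refl_at(spectra, 455L))
  if (!all(is.finite(idx)) || stats::sd(idx) == 0) {
    stop("planted index is degenerate (undefined or zero variance) at this pair")
  }
  signal <- intercept + slope * idx[match(lnc$sample_id, sample_ids(spectra))]
  if (is.null(noise_sd)) noise_sd <- 0.1 * stats::sd(slope * idx)
  noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(length(signal), 0, noise_sd)) else 0
  lnc$lnc <- signal + noise
  attr(lnc, "planted_pair") <- as.integer(pair)
  attr(lnc, "planted_formula") <- formula_id
  lnc
}
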
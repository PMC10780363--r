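#' Default run configuration
#'
#' All knobs of the end-to-end pipeline in one flat list, serializable to
#' JSON. Generator fields mirror [generator_config()]; the remaining fields
#' control preprocessing, the search grid, screening and the model grid.
#'
#' @param seed master seed.
#' @param out output directory.
#' @return named list.
#' @export
default_run_config <- function(seed = 1L, out = "nitrospec-run") {
  list(seed = seed, out = out,
       spectra_file = NULL, lnc_file = NULL,   # NULL: simulate instead of ingest
       plot_noise_sd = 0.15, spectral_noise_sd = 0.005,
       window = 9L, order = 4L,
       stride = 5L, alpha = 0.05,
       models = c("PLSR", "RF", "BPNN"),
       rf_ntree = 600L, bpnn_hidden = 15L, bpnn_max_epochs = 120L,
       plsr_max_lv = 10L, plsr_folds = 10L,
       fraction = 2 / 3, render_figures = FALSE)
}

#' Read a run configuration from a JSON file
#'
#' Missing keys take their [default_run_config()] values; unknown keys are
#' rejected.
#'
#' @param path JSON file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop(sprintf("unknown config key '%s'", unknown[1]))
  cfg[names(user)] <- user
  cfg
}

stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run the full pipeline end to end
#'
#' simulate (or ingest) -> preprocess -> per-layer pair search -> parameter
#' matrices -> screening -> model grid -> metrics, with every artifact
#' written under the output directory and listed, with an MD5 hash, in
#' `manifest.json`.
#'
#' @param config list from [default_run_config()] / [read_run_config()], or
#'   a path to a JSON config file.
#' @param verbose print per-stage timing.
#' @return (invisibly) list with the in-memory results and the output
#'   directory.
#' @export
run_all <- function(config = default_run_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  data <- stage("ingest", verbose, {
    if (!is.null(config$spectra_file)) {
      list(spectra = read_spectra(config$spectra_file),
           lnc = read_lnc(config$lnc_file))
    } else {
      gc <- generator_config(seed = config$seed,
                             plot_noise_sd = config$plot_noise_sd,
                             spectral_noise_sd = config$spectral_noise_sd)
      ex <- simulate_experiment(gc)
      write_spectra(ex$spectra, file.path(out_dir, "spectra.csv"))
      write_lnc(ex$lnc, file.path(out_dir, "lnc.csv"))
      ex
    }
  })

  model_config <- list(
    plsr = list(max_lv = config$plsr_max_lv, folds = config$plsr_folds),
    rf = list(ntree = config$rf_ntree, min_node = 5L),
    bpnn = list(hidden = config$bpnn_hidden,
                max_epochs = config$bpnn_max_epochs, tol = 1e-9))

  grid <- stage("grid", verbose, {
    run_experiment_grid(data$spectra, data$lnc, stride = config$stride,
                        alpha = config$alpha, seed = config$seed,
                        models = config$models, model_config = model_config,
                        window = config$window, order = config$order,
                        fraction = config$fraction)
  })

  stage("write", verbose, {
    write_metrics(grid$metrics, file.path(out_dir, "metrics.csv"))
    pairs_tab <- do.call(rbind, lapply(names(grid$pairs), function(ly) {
      cbind(layer = ly, grid$pairs[[ly]])
    }))
    data.table::fwrite(pairs_tab, file.path(out_dir, "pairs.csv"))
    combos_json <- lapply(grid$combos, function(per_layer) {
      lapply(per_layer, function(df) {
        list(label = attr(df, "label"), members = df$member, r = df$r, p = df$p)
      })
    })
    jsonlite::write_json(combos_json, file.path(out_dir, "combos.json"),
                         auto_unbox = TRUE, digits = NA)
    if (isTRUE(config$render_figures)) {
      for (ly in names(grid$pairs)) {
        best <- grid$metrics[grid$metrics$split %in% "validation", , drop = FALSE]
        surfs <- attr(grid$pairs[[ly]], "surfaces")
        if (!is.null(surfs)) {
          for (f in names(surfs)) {
            render_heatmap(surfs[[f]], file.path(out_dir, sprintf("surface_%s_%s.png", ly, f)))
          }
        }
      }
    }
  })

  files <- setdiff(list.files(out_dir, full.names = TRUE), file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "nitrospec",
    version = as.character(utils::packageVersion("nitrospec")),
    seed = config$seed,
    config = config[setdiff(names(config), "out")],
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(data = data, grid = grid, out = out_dir))
}
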
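#' Write a 1D hologram to plain-text files
#'
#' Writes `<stem>.csv` with columns `index`, `phase_unwrapped_rad`,
#' `phase_wrapped_rad`, `amplitude_mask` and a `<stem>.json` sidecar with the
#' provenance attributes (mode, engine, seed, iterations, gain, error).
#'
#' @param h a `hologram_1d`.
#' @param stem output path without extension.
#' @return invisibly, the CSV path.
#' @export
write_hologram <- function(h, stem) {
  stopifnot(inherits(h, "hologram_1d"))
  csv <- paste0(stem, ".csv")
  utils::write.csv(data.frame(index = seq_len(h$n),
                              phase_unwrapped_rad = h$phase,
                              phase_wrapped_rad = h$phase_wrapped,
                              amplitude_mask = h$mask),
                   csv, row.names = FALSE)
  jsonlite::write_json(list(mode = h$mode, engine = h$engine, seed = h$seed,
                            iterations = h$iterations, gain_max = h$gain_max,
                            error = h$error, n = h$n),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a 1D hologram written by [write_hologram()]
#'
#' @param stem path stem used at write time.
#' @return a `hologram_1d`.
#' @export
read_hologram <- function(stem) {
  d <- utils::read.csv(paste0(stem, ".csv"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(phase = d$phase_unwrapped_rad,
                 phase_wrapped = d$phase_wrapped_rad,
                 mask = d$amplitude_mask,
                 holo_amplitude = NULL,
                 mode = meta$mode, engine = meta$engine, seed = meta$seed,
                 iterations = meta$iterations, gain_max = meta$gain_max,
                 error = meta$error, n = meta$n),
            class = "hologram_1d")
}

#' Write an AOD frequency envelope to CSV
#'
#' Columns `s_mm`, `delta_f_MHz`; carrier and acoustic velocity are stored in
#' a JSON sidecar.
#'
#' @param envelope result of [phase_to_frequency()].
#' @param spec the [aod_spec()] used.
#' @param stem output path without extension.
#' @return invisibly, the CSV path.
#' @export
write_envelope <- function(envelope, spec, stem) {
  csv <- paste0(stem, ".csv")
  utils::write.csv(envelope, csv, row.names = FALSE)
  jsonlite::write_json(list(carrier_MHz = spec$carrier_MHz,
                            v_ac_m_s = spec$v_ac_m_s),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Export a reconstruction as an image
#'
#' Writes the (max-normalized) intensity as 16-bit TIFF or PNG, plus a JSON
#' metrics sidecar. Requires the `tiff`/`png` package for the respective
#' format.
#'
#' @param r a `recon_result` or intensity matrix.
#' @param path output file ending in `.tiff`/`.tif` or `.png`.
#' @return invisibly, `path`.
#' @export
export_image <- function(r, path) {
  img <- if (inherits(r, "recon_result")) r$intensity else r
  img <- img / max(img)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' not available")
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' not available")
    png::writePNG(img, path)
  } else stop("unsupported image format: ", ext)
  if (inherits(r, "recon_result"))
    jsonlite::write_json(r$metrics, paste0(tools::file_path_sans_ext(path), "_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## --- YAML-config driven pipeline ----------------------------------------

require_field <- function(cfg, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (p in parts) {
    if (is.null(node[[p]]))
      stop(sprintf("config validation error: missing field '%s'", path))
    node <- node[[p]]
  }
  node
}

#' Run a retrieve-reconstruct-measure pipeline from a YAML config
#'
#' The config must provide `optics` (`wavelength_nm`, `n_grid`,
#' `pitch_holo_mm`, `focal_mm`), `target` (`fixture`, optional `length_um`),
#' `engine` (`name`: static/dynamic/complex, optional `iterations`,
#' `gain_max`, `apod_gain`) and `seed`. Optional `sweep`
#' (`kind`: apodization/feedback, `steps`, `seeds`) and `output_dir`.
#' All outputs (hologram CSV/JSON, metrics JSON, sweep CSV) are reproducible
#' given the seed.
#'
#' @param config_file path to a YAML file.
#' @return invisibly, a list with the hologram, metrics and any sweep table.
#' @export
run_config <- function(config_file) {
  cfg <- yaml::read_yaml(config_file)
  for (f in c("optics.wavelength_nm", "optics.n_grid", "optics.pitch_holo_mm",
              "optics.focal_mm", "target.fixture", "engine.name", "seed"))
    require_field(cfg, f)
  optics <- optical_config(cfg$optics$wavelength_nm, cfg$optics$n_grid,
                           cfg$optics$pitch_holo_mm, cfg$optics$focal_mm)
  target <- make_fixture(cfg$target$fixture, optics,
                         length_um = cfg$target$length_um)
  engine <- cfg$engine$name
  iters <- cfg$engine$iterations %||%
    (if (engine == "complex") 10L else 200L)
  icfg <- ift_config(iterations = iters, seed = cfg$seed,
                     regularization = engine,
                     gain_max = cfg$engine$gain_max %||% 0.99)
  h <- switch(engine,
              static = gs_static(target, icfg, optics),
              dynamic = gs_dynamic(target, icfg, optics),
              complex = gs_complex(target, icfg, optics),
              stop(sprintf("config validation error: unknown engine.name '%s'", engine)))
  apod <- cfg$engine$apod_gain %||% 0
  if (apod > 0) h <- apodize(h, apod)
  amp <- Mod(field_samples(reconstruct_1d(h, optics)))
  metrics <- list(target_error = target_error(amp, target),
                  speckle_noise = speckle_noise(amp, target),
                  power_efficiency = power_efficiency(h),
                  seed = cfg$seed, engine = engine)
  sweep_tab <- NULL
  if (!is.null(cfg$sweep)) {
    kind <- require_field(cfg, "sweep.kind")
    steps <- cfg$sweep$steps %||% 10L
    seeds <- seq_len(cfg$sweep$seeds %||% 30L) + cfg$seed - 1L
    sweep_tab <- switch(kind,
      apodization = apodization_sweep(target, seq(0, 1, length.out = steps),
                                      seeds, icfg, optics),
      feedback = feedback_sweep(target,
                                inverse_decadic_gain(seq(0, 1, length.out = steps)),
                                seeds, optics = optics),
      stop(sprintf("config validation error: unknown sweep.kind '%s'", kind)))
  }
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_hologram(h, file.path(cfg$output_dir, "hologram"))
    jsonlite::write_json(metrics, file.path(cfg$output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(sweep_tab))
      utils::write.csv(sweep_tab, file.path(cfg$output_dir, "sweep.csv"),
                       row.names = FALSE)
  }
  invisible(list(hologram = h, metrics = metrics, sweep = sweep_tab))
}
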
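# Stack/image I/O, YAML configuration and the end-to-end pipeline runner.
#
# Stacks travel as 32-bit float multi-page TIFFs. The TIFF writer stores
# values in [0, 1], so data are scaled by a power of two (exact in binary
# floating point) recorded in a JSON sidecar next to the file; reading
# restores the original scale. 8/16-bit integer inputs are mapped to [0, 1].

#' Read a 9-frame raw stack
#'
#' Accepts a 9-page TIFF or a directory of 9 single-page TIFFs (sorted
#' lexicographically). Integer inputs arrive scaled to \[0, 1\]; float inputs
#' keep their values. A JSON sidecar (`<path>.json` next to the file, or
#' `stack.json` inside the directory) written by [write_stack()] restores
#' the value scale and any metadata.
#'
#' @param path TIFF file or directory.
#' @return A `sim_stack`.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) != 9L) {
      stop(sprintf("expected 9 single-page TIFFs in '%s', found %d",
                   path, length(files)))
    }
    frames <- lapply(files, function(f) frame_matrix(tiff::readTIFF(f)))
    sidecar <- file.path(path, "stack.json")
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != 9L) {
      stop(sprintf("a raw SIM stack needs exactly 9 frames; '%s' has %d pages",
                   path, length(pages)))
    }
    frames <- lapply(pages, frame_matrix)
    sidecar <- paste0(path, ".json")
  }
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$scale)) {
      frames <- lapply(frames, function(f) f * meta$scale)
    }
  }
  sim_stack(frames, meta = meta)
}

frame_matrix <- function(img) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] != 1L) stop("multi-channel frames are not supported")
    img <- img[, , 1L]
  }
  img
}

#' Write a stack / image as 32-bit float TIFF
#'
#' Values are divided by the smallest power of two bringing them into
#' \[0, 1\] (exact in floating point); the scale is recorded in a JSON
#' sidecar so the round trip is lossless at float32 precision. `write_image`
#' additionally records an offset when the image has negative values.
#' Non-finite values are refused.
#'
#' @param stack a `sim_stack`.
#' @param path output file, conventionally `.tif`.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "sim_stack"))
  frames <- stack$frames
  if (any(vapply(frames, function(f) any(!is.finite(f)), logical(1L)))) {
    stop("refusing to write non-finite pixel values")
  }
  top <- max(0, vapply(frames, max, numeric(1L)))
  scale <- pow2_scale(top)
  frames <- lapply(frames, function(f) pmax(f, 0) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- stack$meta
  sidecar <- c(list(scale = scale), stack_meta_json(meta))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param image a numeric matrix.
#' @export
write_image <- function(image, path) {
  if (any(!is.finite(image))) stop("refusing to write non-finite pixel values")
  offset <- min(image, 0)
  shifted <- image - offset
  scale <- pow2_scale(max(shifted))
  tiff::writeTIFF(shifted / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale, offset = offset),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_image <- function(path) {
  img <- frame_matrix(tiff::readTIFF(path))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- img * (meta$scale %||% 1) + (meta$offset %||% 0)
  }
  img
}

# Smallest power of two >= x (1 for x <= 1): an exactly invertible scale.
pow2_scale <- function(x) {
  if (!is.finite(x) || x <= 1) return(1)
  2^ceiling(log2(x))
}

# Serializable subset of stack metadata.
stack_meta_json <- function(meta) {
  if (is.null(meta)) return(list())
  out <- list()
  if (!is.null(meta$system)) {
    out$optics <- meta$system[c("na", "wavelength_nm", "pixel_nm")]
  }
  if (!is.null(meta$model)) {
    out$illumination <- list(k_theta = meta$model$k_theta,
                             phases_rad = meta$model$phases_rad,
                             m = meta$model$m, i0 = meta$model$i0)
  }
  if (!is.null(meta$noise)) out$noise <- unclass(meta$noise)
  if (!is.null(meta$seed)) out$seed <- meta$seed
  out
}

# ---- configuration ----------------------------------------------------------

pipeline_defaults <- function() {
  list(
    optics = list(na = 1.4, wavelength_nm = 520, pixel_nm = 45,
                  otf_path = NULL),
    illumination = list(orientations_deg = c(0, 60, 120),
                        phases_deg = c(0, 120, 240), period_px = 6,
                        ktheta_frac = 0.8, m = 0.8),
    estimation = list(r_inner_frac = 0.3, r_outer_frac = 1.1, sigma = 0.01,
                      min_significance = 5, refine = TRUE),
    reconstruction = list(w = 0.1, sigma = 0.01, pad_factor = 2,
                          apodization = "none"),
    preprocess = list(enabled = TRUE, reference_index = 1, median_window = 3),
    backend = "serial",
    seed = 1
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML with sections `optics`, `illumination`, `estimation`,
#' `reconstruction`, `preprocess`, and scalar keys `backend`, `seed`.
#' Unknown keys are rejected by name; missing keys take the defaults of
#' `pipeline_defaults`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A validated `pipeline_config` list.
#' @export
read_config <- function(path = NULL) {
  defaults <- pipeline_defaults()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (sec in names(cfg)) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
      if (length(bad)) {
        stop(sprintf("unknown configuration key(s) in '%s': %s", sec,
                     paste(bad, collapse = ", ")))
      }
      defaults[[sec]] <- modifyList(defaults[[sec]], cfg[[sec]])
    } else {
      defaults[[sec]] <- cfg[[sec]]
    }
  }
  validate_config(defaults)
}

validate_config <- function(cfg) {
  o <- cfg$optics
  for (key in c("na", "wavelength_nm", "pixel_nm")) {
    if (is.null(o[[key]]) || !is.numeric(o[[key]]) || o[[key]] <= 0) {
      stop(sprintf("configuration key 'optics.%s' must be a positive number", key))
    }
  }
  if (!cfg$backend %in% list_backends()) {
    stop(sprintf("configuration key 'backend' must be one of: %s",
                 paste(list_backends(), collapse = ", ")))
  }
  if (length(cfg$illumination$orientations_deg) != 3L) {
    stop("configuration key 'illumination.orientations_deg' must list 3 angles")
  }
  structure(cfg, class = "pipeline_config")
}

# ---- pipeline ---------------------------------------------------------------

#' Run the full reconstruction pipeline
#'
#' Reads a raw stack, optionally pre-processes it, estimates the
#' illumination parameters and reconstructs. Writes `recon.tif`, a
#' `widefield.tif` comparison (mean of the 9 raw frames), `params.json`
#' (the estimate) and `manifest.json` (configuration echo, package version,
#' seed, per-stage timings) into `out_dir`. Deterministic given the
#' configuration.
#'
#' @param config a `pipeline_config` from [read_config()] (or `NULL` for
#'   defaults).
#' @param stack_path raw stack (file or directory), see [read_stack()].
#' @param out_dir output directory (created if missing).
#' @return The `sim_reconstruction`, invisibly, with the `sim_fit` attached
#'   as `$params_used`.
#' @export
run_pipeline <- function(config, stack_path, out_dir) {
  if (is.null(config)) config <- read_config(NULL)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(as.integer(config$seed))
  timings <- list()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  stack <- tic("read", read_stack(stack_path))
  shp <- dim(stack$frames[[1L]])
  sys <- optical_system(config$optics$na, config$optics$wavelength_nm,
                        config$optics$pixel_nm, shp)
  otf <- if (!is.null(config$optics$otf_path)) {
    tic("otf", load_measured_otf(config$optics$otf_path, sys$kc_px,
                                 sys$pixel_nm))
  } else {
    analytic_otf(sys, shp)
  }
  if (isTRUE(config$preprocess$enabled)) {
    stack <- tic("preprocess",
                 preprocess_stack(stack, config$preprocess$reference_index,
                                  config$preprocess$median_window))
  }
  est <- tic("estimate", estimate_all(
    stack, otf,
    r_inner_frac = config$estimation$r_inner_frac,
    r_outer_frac = config$estimation$r_outer_frac,
    sigma = config$estimation$sigma, m = config$illumination$m,
    min_significance = config$estimation$min_significance,
    refine = isTRUE(config$estimation$refine)))
  rc <- recon_config(w = config$reconstruction$w,
                     sigma = config$reconstruction$sigma,
                     pad_factor = config$reconstruction$pad_factor,
                     apodization = config$reconstruction$apodization)
  recon <- tic("reconstruct",
               reconstruct(stack, est, otf, rc, backend = config$backend))
  tic("write", {
    write_image(recon$image, file.path(out_dir, "recon.tif"))
    write_image(recon$widefield, file.path(out_dir, "widefield.tif"))
    jsonlite::write_json(params_json(est), file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  jsonlite::write_json(
    list(package = "stripesim",
         version = as.character(packageVersion("stripesim")),
         seed = config$seed, config = unclass(config),
         input = basename(stack_path), input_shape = shp,
         timings_s = timings),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(recon)
}

# params.json schema: orientations x {k, phases_deg, peak_px}, plus m.
params_json <- function(est) {
  list(
    orientations = lapply(1:3, function(o) {
      idx <- 3L * (o - 1L) + 1:3
      list(k = as.numeric(est$k_theta[o, ]),
           k_cells = as.numeric(est$k_cells[o, ]),
           theta_deg = est$orientation_deg[o],
           phases_deg = as.numeric(est$phases_rad[idx]) * 180 / pi,
           peak_px = lapply(idx, function(i) as.numeric(est$peaks_cells[i, ])))
    }),
    m = est$m, m_est = est$m_est, significance = est$significance
  )
}
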
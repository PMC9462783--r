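# Binary stripe patterns for a digital micromirror device (DMD).
#
# A DMD mirror is either on or off, so stripe illumination is programmed as a
# binary square wave: `duty_on_px` mirrors on followed by
# `period_px - duty_on_px` mirrors off along the stripe normal. Phase steps
# are realized as integer pixel shifts, which is why the canonical three-step
# (120 degree) acquisition needs a period of at least 6 px: the 120 degree
# step then corresponds to an exact 2 px shift.

#' Pixel shift realizing a phase step of a binary stripe pattern
#'
#' A phase step of `phase_rad` on a pattern with `period_px` pixels per
#' period corresponds to a shift of `period_px * phase_rad / (2*pi)` pixels
#' along the stripe normal. Mirrors sit on an integer grid, so the shift is
#' rounded to the nearest pixel; when the ideal shift is non-integer the
#' function warns and records the realized (rounded) phase in the
#' `"realized_phase_rad"` attribute, with `"exact"` set to `FALSE`.
#'
#' @param period_px integer pixels per stripe period (>= 2).
#' @param phase_rad desired phase step in radians.
#' @return Integer pixel shift with attributes `exact` (logical) and
#'   `realized_phase_rad` (the phase actually produced by the rounded shift).
#' @examples
#' pixel_shift_for_phase(6, 2 * pi / 3)  # 2 px: the canonical 120 degree step
#' @export
pixel_shift_for_phase <- function(period_px, phase_rad) {
  if (!is.numeric(period_px) || length(period_px) != 1L || period_px < 2 ||
      period_px != round(period_px)) {
    stop("`period_px` must be a single integer >= 2")
  }
  ideal <- period_px * phase_rad / (2 * pi)
  shift <- round(ideal)
  exact <- isTRUE(all.equal(ideal, shift, tolerance = 1e-9))
  if (!exact) {
    warning(sprintf(
      "phase %.6g rad is not an integer pixel shift at period %d (ideal %.4f px); rounding to %d px",
      phase_rad, as.integer(period_px), ideal, as.integer(shift)))
  }
  structure(as.integer(shift), exact = exact,
            realized_phase_rad = 2 * pi * shift / period_px)
}

#' Generate a binary DMD stripe pattern
#'
#' Pixel `(x, y)` (x = column - 1, y = row - 1, origin top-left) is on iff
#' `frac((x*cos(theta) + y*sin(theta)) / period_px - phase_rad/(2*pi)) <
#' duty_on_px / period_px`. For axis-aligned orientations this reproduces the
#' exact integer mirror logic (e.g. three on, three off at period 6); oblique
#' orientations are rasterized by thresholding the continuous stripe phase,
#' so the exact duty fraction is only guaranteed at 0 and 90 degrees.
#'
#' @param width,height pattern size in pixels.
#' @param period_px integer pixels per period.
#' @param orientation_deg stripe normal direction in degrees (0 = stripes
#'   vary along x).
#' @param phase_rad pattern phase in radians.
#' @param duty_on_px integer on-pixels per period, `1 <= duty_on_px <
#'   period_px`.
#' @return A `dmd_pattern`: list with `pixels` (0/1 integer matrix),
#'   `period_px`, `orientation_deg`, `phase_rad` (nominal),
#'   `realized_phase_rad` (after pixel rounding, for axis-aligned patterns)
#'   and `duty_on_px`.
#' @examples
#' p <- generate_stripe_pattern(6, 1, 6, 0, 0, 3)
#' p$pixels  # 1 1 1 0 0 0
#' @export
generate_stripe_pattern <- function(width, height, period_px, orientation_deg,
                                    phase_rad, duty_on_px) {
  if (width < 1 || height < 1) stop("`width` and `height` must be positive")
  if (period_px < 2 || period_px != round(period_px)) {
    stop("`period_px` must be an integer >= 2")
  }
  if (duty_on_px < 1 || duty_on_px >= period_px ||
      duty_on_px != round(duty_on_px)) {
    stop("`duty_on_px` must be an integer with 1 <= duty_on_px < period_px")
  }
  theta <- orientation_deg * pi / 180
  g <- coord_grids(c(height, width))
  u <- (g$x * cos(theta) + g$y * sin(theta)) / period_px - phase_rad / (2 * pi)
  frac <- u - floor(u)
  on <- matrix(as.integer(frac < duty_on_px / period_px - 1e-12 |
                            abs(frac) < 1e-12 | abs(frac - 1) < 1e-12),
               height, width)
  realized <- if (orientation_deg %% 90 == 0) {
    s <- suppressWarnings(pixel_shift_for_phase(period_px, phase_rad))
    attr(s, "realized_phase_rad")
  } else {
    phase_rad
  }
  structure(list(pixels = on, period_px = as.integer(period_px),
                 orientation_deg = orientation_deg, phase_rad = phase_rad,
                 realized_phase_rad = realized,
                 duty_on_px = as.integer(duty_on_px)),
            class = "dmd_pattern")
}

#' Ordered set of 9 stripe patterns (3 orientations x 3 phases)
#'
#' Patterns are ordered orientation-major, phase-minor: pattern
#' `3*(i-1) + j` has the i-th orientation and j-th phase, matching the frame
#' order of raw acquisition stacks.
#'
#' @inheritParams generate_stripe_pattern
#' @param orientations_deg,phases_rad numeric vectors of exactly 3 values.
#' @return A list of 9 [generate_stripe_pattern()] results, class
#'   `dmd_pattern_set`.
#' @export
pattern_set <- function(width, height,
                        orientations_deg = c(0, 60, 120),
                        phases_rad = c(0, 2 * pi / 3, 4 * pi / 3),
                        period_px = 6, duty_on_px = 3) {
  if (length(orientations_deg) != 3L) stop("`orientations_deg` must have length 3")
  if (length(phases_rad) != 3L) stop("`phases_rad` must have length 3")
  out <- vector("list", 9L)
  for (i in 1:3) for (j in 1:3) {
    out[[3L * (i - 1L) + j]] <- generate_stripe_pattern(
      width, height, period_px, orientations_deg[i], phases_rad[j], duty_on_px)
  }
  class(out) <- "dmd_pattern_set"
  out
}

#' Write / read stripe patterns as 1-bit-content PNG images
#'
#' `write_patterns` writes the 9 patterns as grayscale PNGs named
#' `p{orientation index}_{phase index}.png` (indices 0-based) plus a
#' `patterns.json` sidecar with the nominal and realized phases.
#' `read_pattern` loads one PNG back into a 0/1 integer matrix.
#'
#' @param patterns a `dmd_pattern_set`.
#' @param dir output directory (created if missing).
#' @return `write_patterns` returns the written file paths invisibly;
#'   `read_pattern` returns a 0/1 integer matrix.
#' @export
write_patterns <- function(patterns, dir) {
  stopifnot(inherits(patterns, "dmd_pattern_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(9L)
  meta <- vector("list", 9L)
  for (n in 1:9) {
    i <- (n - 1L) %/% 3L
    j <- (n - 1L) %% 3L
    p <- patterns[[n]]
    paths[n] <- file.path(dir, sprintf("p%d_%d.png", i, j))
    png::writePNG(p$pixels + 0, paths[n])  # writePNG wants doubles, not ints
    meta[[n]] <- list(file = basename(paths[n]),
                      orientation_deg = p$orientation_deg,
                      period_px = p$period_px, duty_on_px = p$duty_on_px,
                      phase_rad = p$phase_rad,
                      realized_phase_rad = p$realized_phase_rad)
  }
  jsonlite::write_json(meta, file.path(dir, "patterns.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_patterns
#' @param path PNG file to read.
#' @export
read_pattern <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(img > 0.5), nrow(img), ncol(img))
}

#' Sample-plane stripe period in nanometres
#'
#' The physical length of one illumination stripe period given its measured
#' period in sample-plane pixels and the sample-space pixel size.
#'
#' @param period_px stripe period in sample-plane pixels per cycle.
#' @param pixel_nm sample-space pixel size in nm.
#' @return Period in nm per cycle.
#' @examples
#' sample_period_nm(33, 45)  # 1485 nm/cycle
#' @export
sample_period_nm <- function(period_px, pixel_nm) {
  if (period_px <= 0 || pixel_nm <= 0) stop("inputs must be positive")
  period_px * pixel_nm
}

#' @export
print.dmd_pattern <- function(x, ...) {
  cat(sprintf(
    "DMD stripe pattern: %d x %d px, period %d px (%d on), theta = %g deg, phase = %g rad\n",
    ncol(x$pixels), nrow(x$pixels), x$period_px, x$duty_on_px,
    x$orientation_deg, x$phase_rad))
  invisible(x)
}

#' @export
print.dmd_pattern_set <- function(x, ...) {
  cat("Set of 9 DMD stripe patterns (orientation-major, phase-minor):\n")
  for (p in x) print(p)
  invisible(x)
}
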
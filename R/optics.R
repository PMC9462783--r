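# Diffraction-limited incoherent optical model.
#
# The microscope acts as a low-pass filter: its optical transfer function
# (OTF) is zero beyond the cutoff k_c = 2 NA / lambda (cycles per length; the
# angular-frequency convention multiplies this by 2*pi, and is documented but
# never stored). Internally frequencies are handled in cycles/px on the
# working grid; the pixel size converts to cycles/nm at the interface.

#' Describe the optical system
#'
#' @param na numerical aperture of the objective (> 0).
#' @param wavelength_nm emission wavelength in nm.
#' @param pixel_nm sample-space pixel size in nm.
#' @param shape working grid size `c(rows, cols)`.
#' @return An `optical_system` with the derived cutoff in cycles/nm
#'   (`kc_nm`) and cycles/px (`kc_px`). Warns if the pixel size violates the
#'   Nyquist condition `pixel_nm <= 1 / (2 * kc_nm)` needed for alias-free
#'   simulation.
#' @examples
#' optical_system(1.4, 520, 45, c(256, 256))
#' @export
optical_system <- function(na, wavelength_nm, pixel_nm, shape = c(512L, 512L)) {
  if (na <= 0 || wavelength_nm <= 0 || pixel_nm <= 0) {
    stop("`na`, `wavelength_nm` and `pixel_nm` must be positive")
  }
  if (length(shape) != 2L || any(shape < 1)) stop("`shape` must be c(rows, cols)")
  kc_nm <- cutoff_frequency(na, wavelength_nm)
  kc_px <- as.numeric(kc_nm) * pixel_nm
  if (kc_px > 0.5) {
    warning(sprintf(
      "pixel size %g nm undersamples the cutoff (k_c = %.4g cycles/px > 0.5); simulation will alias",
      pixel_nm, kc_px))
  }
  structure(list(na = na, wavelength_nm = wavelength_nm, pixel_nm = pixel_nm,
                 shape = as.integer(shape), kc_nm = kc_nm, kc_px = kc_px),
            class = "optical_system")
}

#' Incoherent cutoff frequency
#'
#' `k_c = 2 NA / lambda` in cycles/nm; the minimum resolvable stripe period
#' is its reciprocal, `lambda / (2 NA)`.
#'
#' @inheritParams optical_system
#' @return Cutoff in cycles/nm, with the period in nm in attribute
#'   `"period_nm"`.
#' @examples
#' cutoff_frequency(1.4, 520)  # ~5.385e-3 cycles/nm, 185.7 nm period
#' @export
cutoff_frequency <- function(na, wavelength_nm) {
  if (na <= 0 || wavelength_nm <= 0) stop("`na` and `wavelength_nm` must be positive")
  kc <- 2 * na / wavelength_nm
  structure(kc, period_nm = 1 / kc)
}

#' Diffraction-limited OTF of a circular pupil
#'
#' The standard incoherent OTF `O(rho) = (2/pi) * (acos(rho) -
#' rho*sqrt(1-rho^2))` for `rho = |k|/k_c <= 1` and 0 beyond, evaluated on
#' the centered frequency grid of the system. The sharp cutoff (rather than
#' a Gaussian approximation) is what makes spectral support extension
#' measurable.
#'
#' @param system an [optical_system()].
#' @param shape optional grid override `c(rows, cols)`.
#' @return An `otf`: list with `values` (centered, DC = 1), `kc_px`,
#'   `pixel_nm` and `source = "analytic"`.
#' @export
analytic_otf <- function(system, shape = system$shape) {
  stopifnot(inherits(system, "optical_system"))
  if (any(shape < 8)) stop("grid too small for an OTF (need at least 8 x 8)")
  rho <- freq_radius(shape) / system$kc_px
  values <- otf_radial(rho)
  structure(list(values = values, kc_px = system$kc_px,
                 pixel_nm = system$pixel_nm, source = "analytic"),
            class = "otf")
}

# Radial incoherent-pupil OTF profile; rho = |k|/k_c.
otf_radial <- function(rho) {
  v <- numeric(length(rho))
  inside <- rho < 1
  r <- rho[inside]
  v[inside] <- (2 / pi) * (acos(r) - r * sqrt(1 - r^2))
  dim(v) <- dim(rho)
  v
}

#' Load a measured OTF from a 2D float image
#'
#' The image must hold the OTF magnitude on the centered frequency grid (DC
#' at `floor(n/2)+1`). It is renormalized so the DC value is 1; negative
#' values are clipped to zero with a warning.
#'
#' @param path a single-page TIFF file; a [write_image()] sidecar is honoured
#'   when present.
#' @param kc_px cutoff frequency of the setup in cycles/px (from
#'   [optical_system()] or calibration).
#' @param pixel_nm sample-space pixel size in nm (metadata only).
#' @return An `otf` with `source = "measured"`.
#' @export
load_measured_otf <- function(path, kc_px, pixel_nm = NA_real_) {
  img <- read_image(path)
  if (length(dim(img)) != 2L) stop("measured OTF must be a single-channel 2D image")
  if (all(img == 0)) stop("measured OTF is all zero")
  if (any(img < 0)) {
    warning("measured OTF contains negative values; clipping to zero")
    img[img < 0] <- 0
  }
  dc <- img[dc_index(nrow(img)), dc_index(ncol(img))]
  if (dc <= 0) stop("measured OTF has a non-positive DC value")
  structure(list(values = img / dc, kc_px = kc_px, pixel_nm = pixel_nm,
                 source = "measured"), class = "otf")
}

#' Point spread function from an OTF
#'
#' Inverse Fourier transform of the OTF, real part, centered on the grid and
#' normalized to unit sum.
#'
#' @param otf an `otf` object.
#' @return A real matrix (the PSF), same shape as the OTF.
#' @export
psf_from_otf <- function(otf) {
  stopifnot(inherits(otf, "otf"))
  psf <- Re(ifft2(ifftshift2(otf$values)))
  psf <- fftshift2(psf)
  psf / sum(psf)
}

#' @export
print.optical_system <- function(x, ...) {
  cat(sprintf(
    "Optical system: NA %.3g, lambda %g nm, pixel %g nm, grid %d x %d\n",
    x$na, x$wavelength_nm, x$pixel_nm, x$shape[1L], x$shape[2L]))
  cat(sprintf("  cutoff: %.4g cycles/nm (%.1f nm period), %.4g cycles/px\n",
              x$kc_nm, 1 / x$kc_nm, x$kc_px))
  invisible(x)
}

#' @export
print.otf <- function(x, ...) {
  cat(sprintf("OTF (%s): %d x %d grid, k_c = %.4g cycles/px\n",
              x$source, nrow(x$values), ncol(x$values), x$kc_px))
  invisible(x)
}
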
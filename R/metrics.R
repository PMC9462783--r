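# Resolution metrics: point-source FWHM and spectral support radius.
#
# Used to quantify the resolution gain of a reconstruction against its
# widefield counterpart. Both metrics are grid-aware: pass `pixel_nm` to get
# physical units (remember that a pad_factor-2 reconstruction has pixels half
# the size of the input's).

#' Full width at half maximum of a point source
#'
#' Measures the FWHM of a peak in `image` along the x and y axes through the
#' peak pixel. The half-maximum crossings on each side are located by linear
#' interpolation between samples; the reported `fwhm` is the mean of the two
#' axis widths. The profile baseline is taken as the minimum of the profile
#' within `halfwin` pixels of the peak.
#'
#' @param image numeric matrix.
#' @param center optional `c(x, y)` pixel coordinate (1-based, col/row) near
#'   the peak; the brightest pixel within `halfwin` of it is used. Default:
#'   global argmax.
#' @param pixel_nm physical pixel pitch; widths are returned in these units
#'   (default 1 = pixels).
#' @param halfwin half-width of the measurement window in pixels.
#' @return List with `fwhm`, `fwhm_x`, `fwhm_y` (in `pixel_nm` units) and
#'   `peak` (the `c(x, y)` pixel used).
#' @export
measure_fwhm <- function(image, center = NULL, pixel_nm = 1, halfwin = 12L) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(center)) {
    ij <- which(image == max(image), arr.ind = TRUE)[1L, ]
    px <- ij[["col"]]; py <- ij[["row"]]
  } else {
    cx <- round(center[1L]); cy <- round(center[2L])
    xs <- max(1L, cx - halfwin):min(nc, cx + halfwin)
    ys <- max(1L, cy - halfwin):min(nr, cy + halfwin)
    sub <- image[ys, xs, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    px <- xs[ij[["col"]]]; py <- ys[ij[["row"]]]
  }
  prof_x <- image[py, max(1L, px - halfwin):min(nc, px + halfwin)]
  prof_y <- image[max(1L, py - halfwin):min(nr, py + halfwin), px]
  fx <- profile_fwhm(prof_x, which(max(1L, px - halfwin):min(nc, px + halfwin) == px))
  fy <- profile_fwhm(prof_y, which(max(1L, py - halfwin):min(nr, py + halfwin) == py))
  list(fwhm = mean(c(fx, fy)) * pixel_nm, fwhm_x = fx * pixel_nm,
       fwhm_y = fy * pixel_nm, peak = c(x = px, y = py))
}

# Width at half maximum of a 1-D profile around index `ipk`, in samples.
profile_fwhm <- function(profile, ipk) {
  base <- min(profile)
  half <- base + (profile[ipk] - base) / 2
  # left crossing
  left <- NA_real_
  for (i in seq(ipk, 2L)) {
    if (profile[i - 1L] < half && profile[i] >= half) {
      left <- (i - 1L) + (half - profile[i - 1L]) / (profile[i] - profile[i - 1L])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, length(profile) - 1L)) {
    if (profile[i + 1L] < half && profile[i] >= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1L])
      break
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    stop("half-maximum crossing not found inside the measurement window")
  }
  right - left
}

#' Radius of the spectral support of an image
#'
#' Largest frequency radius (cycles/px of `image`'s own grid) at which the
#' per-radius maximum of the centered spectrum magnitude still exceeds
#' `threshold_frac` of the global maximum. Radii are binned at the grid's
#' frequency resolution.
#'
#' @param image numeric matrix.
#' @param threshold_frac support threshold as a fraction of the spectrum's
#'   maximum magnitude (default 0.01 = the 1 percent level).
#' @return Support radius in cycles/px.
#' @export
spectral_support_radius <- function(image, threshold_frac = 0.01) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("`threshold_frac` must be in (0, 1)")
  }
  mag <- Mod(fftshift2(fft2(image)))
  r <- freq_radius(dim(image))
  n <- min(dim(image))
  bin <- as.integer(round(r * n))  # integer cells on the finer axis
  top <- tapply(as.numeric(mag), bin, max)
  radii <- as.numeric(names(top)) / n
  keep <- top >= threshold_frac * max(mag)
  if (!any(keep)) return(0)
  max(radii[keep])
}
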
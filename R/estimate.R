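# Estimation of the experimental illumination parameters from raw stacks.
#
# Nominal DMD phases and frequencies never survive the optical path exactly,
# so both are measured from the data. The modulation peak is located in a
# band-pass-limited search of the frequency spectrum ("phase of peak"); the
# frequency vector is refined to sub-pixel precision by OTF-cross-weighted
# correlation between the separated first-order band and the 0th band.
#
# Phase estimation detail: the spectrum value at the modulation peak is
# (m/2) e^{i phi} S~(0) OTF(k_theta) plus leakage from the widefield (0th)
# band. The widefield component is identical in the three frames of one
# orientation, so subtracting the orientation mean removes it exactly for
# equispaced phase steps; phases are then read as the complex argument of
# the single-frequency DTFT of the mean-subtracted frame at the refined
# sub-pixel frequency. The plain integer-bin estimator is available as
# `estimate_phase`.

#' Annular band-pass mask on the centered frequency grid
#'
#' 1 on `r_inner <= |k| <= r_outer` (cycles/px), 0 elsewhere; the DC bin is
#' always excluded.
#'
#' @param shape grid `c(rows, cols)`.
#' @param r_inner,r_outer annulus radii in cycles/px, `0 < r_inner <
#'   r_outer`.
#' @return A 0/1 integer matrix.
#' @export
bandpass_mask <- function(shape, r_inner, r_outer) {
  if (r_inner <= 0 || r_inner >= r_outer) {
    stop("need 0 < r_inner < r_outer")
  }
  r <- freq_radius(shape)
  m <- matrix(as.integer(r >= r_inner & r <= r_outer), shape[1L], shape[2L])
  m[dc_index(shape[1L]), dc_index(shape[2L])] <- 0L
  m
}

#' Wiener pre-filter (regularized OTF compensation)
#'
#' `conj(OTF) * D / (|OTF| + sigma)` elementwise: suppresses out-of-band
#' noise and flattens the OTF weighting ahead of peak finding and phase
#' correlation. Where the OTF is zero the output is zero.
#'
#' @param spectrum complex matrix (centered).
#' @param otf an `otf` object or a numeric matrix of the same shape.
#' @param sigma small positive regularization constant.
#' @param backend element-wise execution backend.
#' @return Complex matrix.
#' @export
wiener_prefilter <- function(spectrum, otf, sigma = 0.01,
                             backend = getOption("stripesim.backend", "serial")) {
  if (sigma <= 0) stop("`sigma` must be positive")
  v <- if (inherits(otf, "otf")) otf$values else otf
  if (!identical(dim(v), dim(spectrum))) stop("OTF and spectrum shapes disagree")
  elementwise("wiener_ratio", spectrum, v, sigma, backend = backend)
}

#' Locate the modulation peak in a masked spectrum
#'
#' Argmax of `|spectrum|` over the mask, reported in integer grid cells
#' relative to DC as `c(kx, ky)`. Of the conjugate +/- pair the
#' positive-`kx` member is returned (ties broken toward positive `ky`).
#' The peak's significance is its magnitude over the median masked
#' magnitude; below `min_significance` (or when the masked region is empty
#' or identically zero) a no-peak error is raised.
#'
#' @param frame_spectrum complex (or magnitude) matrix, centered.
#' @param mask 0/1 matrix from [bandpass_mask()].
#' @param min_significance minimal peak-to-median ratio (default 0: report
#'   whatever argmax is found).
#' @return List with `coord_cells`, `magnitude`, `significance`.
#' @export
find_modulation_peak <- function(frame_spectrum, mask, min_significance = 0) {
  if (!identical(dim(mask), dim(frame_spectrum))) stop("mask shape disagrees")
  mag <- Mod(frame_spectrum)
  sel <- mask > 0
  if (!any(sel)) stop("no peak: mask excludes the whole spectrum")
  vals <- mag[sel]
  peak_mag <- max(vals)
  if (peak_mag == 0) stop("no peak: masked spectrum is identically zero")
  idx <- which(mag == peak_mag & sel, arr.ind = TRUE)[1L, ]
  kx <- idx[["col"]] - dc_index(ncol(mag))
  ky <- idx[["row"]] - dc_index(nrow(mag))
  if (kx < 0 || (kx == 0 && ky < 0)) { kx <- -kx; ky <- -ky }
  signif <- peak_mag / max(median(vals), .Machine$double.xmin)
  if (signif < min_significance) {
    stop(sprintf("no peak: significance %.2f below threshold %.2f",
                 signif, min_significance))
  }
  list(coord_cells = c(kx = as.integer(kx), ky = as.integer(ky)),
       magnitude = peak_mag, significance = signif)
}

#' Phase of peak (integer bin)
#'
#' The full-quadrant arctangent of the complex spectrum value at the peak
#' coordinate: `atan2(Im, Re)` of `D~(k_peak)`.
#'
#' @param frame_spectrum complex matrix, centered.
#' @param peak_coord integer `c(kx, ky)` cells relative to DC.
#' @return Phase in `(-pi, pi]`.
#' @export
estimate_phase <- function(frame_spectrum, peak_coord) {
  r <- dc_index(nrow(frame_spectrum)) + peak_coord[2L]
  c <- dc_index(ncol(frame_spectrum)) + peak_coord[1L]
  if (r < 1 || r > nrow(frame_spectrum) || c < 1 || c > ncol(frame_spectrum)) {
    stop("peak coordinate outside the grid")
  }
  v <- frame_spectrum[r, c]
  if (Mod(v) == 0) stop("undefined phase: spectrum value at the peak is zero")
  wrap_pi(Arg(v))
}

# Sub-pixel phase of peak: argument of the single-frequency DTFT of the
# (typically mean-subtracted) real-space frame at frequency k (cycles/px).
phase_at_frequency <- function(frame, k) {
  v <- dtft_point(frame, k)
  if (Mod(v) == 0) stop("undefined phase: DTFT value at the peak frequency is zero")
  wrap_pi(Arg(v))
}

#' Refine the illumination frequency to sub-pixel precision
#'
#' Separates the three phase-stepped frames of one orientation into the 0th
#' and first-order bands, cross-weights each band by the *other* band's
#' (shifted) OTF, and correlates the real-space counterparts. With weights
#' `B0(k) * OTF(k + k_est)` and `B+(k) * OTF(k - k_est)` both terms of the
#' correlation carry the identical weight `OTF(u) * OTF(u + k_theta)` at
#' source frequency `u`, so the correlation magnitude is (to first order) an
#' autocorrelation — its peak sits at the true frequency with no weighting
#' bias. The peak is located by a three-stage zoomed DTFT (+/- 1.5 cells at
#' 0.1, then 0.02, then 0.002-cell granularity) and the whole step is
#' iterated once so the weights use the refined frequency.
#'
#' The separation here uses the *raw* spectra: a Wiener pre-filter would add
#' a weight to one band that the other does not share and re-introduce a
#' (small) bias.
#'
#' @param frames list of the 3 real-space frames of one orientation.
#' @param coarse_peak integer `c(kx, ky)` cells from [find_modulation_peak()].
#' @param otf an `otf` object matching the frame shape.
#' @param sigma pre-filter constant, used only for the default coarse phase
#'   estimate.
#' @param m modulation depth used for separation.
#' @param phases optional 3 phases for the separation matrix; default:
#'   integer-bin phase of peak of the pre-filtered spectra.
#' @return `c(kx, ky)` in cycles/px with attributes `cells` and `converged`.
#'   If the refinement lands more than 1 cell from the coarse peak it falls
#'   back to the coarse value with a warning (`converged = FALSE`).
#' @export
refine_frequency_subpixel <- function(frames, coarse_peak, otf, sigma = 0.01,
                                      m = 0.8, phases = NULL) {
  stopifnot(length(frames) == 3L)
  nr <- nrow(frames[[1L]]); nc <- ncol(frames[[1L]])
  spectra <- lapply(frames, function(f) fftshift2(fft2(f)))
  if (is.null(phases)) {
    filt <- lapply(spectra, wiener_prefilter, otf = otf, sigma = sigma)
    phases <- vapply(filt, estimate_phase, numeric(1L), peak_coord = coarse_peak)
  }
  M <- separation_matrix(phases, m)
  bands <- separate_components(spectra, M)
  k0 <- c(coarse_peak[1L] / nc, coarse_peak[2L] / nr)
  zoom_max <- function(q, center, half_cells, step_cells) {
    kx <- center[1L] + seq(-half_cells, half_cells, by = step_cells) / nc
    ky <- center[2L] + seq(-half_cells, half_cells, by = step_cells) / nr
    z <- Mod(dtft_zoom(q, kx, ky))
    ij <- which(z == max(z), arr.ind = TRUE)[1L, ]
    c(kx[ij[["col"]]], ky[ij[["row"]]])
  }
  k <- k0
  for (iter in 1:2) {
    cells <- c(k[1L] * nc, k[2L] * nr)
    # shifted_otf(v, s) samples v at (k - s): -cells gives OTF(k + k_est).
    u0 <- bands$order0 * shifted_otf(otf$values, -cells)
    up <- bands$plus * shifted_otf(otf$values, +cells)
    q <- ifft2(ifftshift2(up)) * Conj(ifft2(ifftshift2(u0)))
    k1 <- zoom_max(q, k, 1.5, 0.1)
    k1 <- zoom_max(q, k1, 0.2, 0.02)
    k <- zoom_max(q, k1, 0.03, 0.002)
  }
  cells <- c(k[1L] * nc, k[2L] * nr)
  if (max(abs(cells - coarse_peak)) > 1 + 1e-9) {
    warning("sub-pixel refinement diverged more than 1 px from the coarse peak; falling back")
    k <- k0
    cells <- as.numeric(coarse_peak)
    converged <- FALSE
  } else {
    converged <- TRUE
  }
  structure(c(kx = k[1L], ky = k[2L]), cells = cells, converged = converged)
}

#' Estimate all illumination parameters of a raw stack
#'
#' For each orientation: subtract the orientation mean (the widefield
#' component), locate the modulation peak of the frame-to-widefield
#' cross-correlation spectra inside the band-pass annulus, refine the
#' frequency by OTF-cross-weighted band correlation, and read the 9 phases
#' as the DTFT argument of the
#' mean-subtracted frames at the refined frequency. The modulation depth is
#' user-supplied by default; `m_est` additionally reports a peak-to-DC
#' magnitude estimate per orientation (experimental).
#'
#' @param stack a `sim_stack`.
#' @param otf an `otf`; default: analytic OTF of the stack's recorded
#'   optical system.
#' @param r_inner_frac,r_outer_frac annulus radii as fractions of the cutoff
#'   (defaults 0.3 and 1.1).
#' @param sigma Wiener pre-filter constant.
#' @param m modulation depth assumed for band separation (default 0.8).
#' @param min_significance peak significance threshold (default 5).
#' @param refine logical: sub-pixel refinement (default TRUE).
#' @return A `sim_fit`: `k_theta` (3 x 2, cycles/px), `k_cells` (3 x 2),
#'   `orientation_deg` (3), `phases_rad` (9), `peaks_cells` (9 x 2 integer),
#'   `m`, `m_est`, `significance`, `converged`, `shape`, `kc_px`.
#' @export
estimate_all <- function(stack, otf = NULL, r_inner_frac = 0.3,
                         r_outer_frac = 1.1, sigma = 0.01, m = 0.8,
                         min_significance = 5, refine = TRUE) {
  stopifnot(inherits(stack, "sim_stack"))
  shp <- dim(stack$frames[[1L]])
  if (is.null(otf)) {
    sys <- stack$meta$system
    if (is.null(sys)) stop("no OTF given and the stack records no optical system")
    otf <- analytic_otf(sys, shp)
  }
  kc <- otf$kc_px
  mask <- bandpass_mask(shp, r_inner_frac * kc, r_outer_frac * kc)
  k_theta <- matrix(NA_real_, 3L, 2L, dimnames = list(NULL, c("kx", "ky")))
  k_cells <- matrix(NA_real_, 3L, 2L)
  phases <- numeric(9L)
  peaks <- matrix(NA_integer_, 9L, 2L, dimnames = list(NULL, c("kx", "ky")))
  signif <- numeric(3L)
  m_est <- numeric(3L)
  converged <- logical(3L)
  for (o in 1:3) {
    res <- tryCatch({
      idx <- 3L * (o - 1L) + 1:3
      fr <- stack$frames[idx]
      wf <- (fr[[1L]] + fr[[2L]] + fr[[3L]]) / 3
      d <- lapply(fr, function(f) f - wf)
      spectra <- lapply(d, function(f) fftshift2(fft2(f)))
      filt <- lapply(spectra, wiener_prefilter, otf = otf, sigma = sigma)
      # Coarse peak: cross-correlation of each mean-subtracted frame with the
      # orientation widefield. |FFT(d_n * wf)|(v) is the correlation between
      # the +/-1 bands (in d_n) and the 0th band (in wf) at integer lag v; it
      # peaks at +/- k_theta regardless of the sample's own spectral shape,
      # where the plain band magnitude can peak toward DC for low-pass
      # samples (the band carries S~(k - k_theta), largest near k_theta - 0).
      corr <- lapply(d, function(f) Mod(fftshift2(fft2(f * wf))))
      pk <- find_modulation_peak(corr[[1L]] + corr[[2L]] + corr[[3L]], mask,
                                 min_significance = min_significance)
      frame_peaks <- t(vapply(corr, function(s) {
        find_modulation_peak(s, mask)$coord_cells
      }, integer(2L)))
      coarse_phases <- vapply(seq_len(3L), function(j) {
        estimate_phase(filt[[j]], pk$coord_cells)
      }, numeric(1L))
      if (refine) {
        k <- refine_frequency_subpixel(fr, pk$coord_cells, otf, sigma = sigma,
                                       m = m, phases = coarse_phases)
      } else {
        k <- structure(c(pk$coord_cells[1L] / shp[2L],
                         pk$coord_cells[2L] / shp[1L]),
                       cells = as.numeric(pk$coord_cells), converged = TRUE)
      }
      ph <- vapply(d, phase_at_frequency, numeric(1L), k = as.numeric(k))
      peak_amp <- vapply(d, function(f) Mod(dtft_point(f, as.numeric(k))),
                         numeric(1L))
      wf_dc <- sum(wf)
      otf_at_k <- otf_value_at(otf, as.numeric(k))
      list(k = k, phases = ph, frame_peaks = frame_peaks,
           significance = pk$significance,
           m_est = if (wf_dc > 0 && otf_at_k > 0)
             mean(2 * peak_amp / (wf_dc * otf_at_k)) else NA_real_)
    }, error = function(e) {
      stop(sprintf("orientation %d: %s", o, conditionMessage(e)), call. = FALSE)
    })
    k_theta[o, ] <- as.numeric(res$k)
    k_cells[o, ] <- attr(res$k, "cells")
    converged[o] <- attr(res$k, "converged")
    phases[3L * (o - 1L) + 1:3] <- res$phases
    peaks[3L * (o - 1L) + 1:3, ] <- res$frame_peaks
    signif[o] <- res$significance
    m_est[o] <- res$m_est
  }
  structure(list(
    k_theta = k_theta, k_cells = k_cells,
    orientation_deg = atan2(k_theta[, 2L], k_theta[, 1L]) * 180 / pi,
    phases_rad = wrap_pi(phases), peaks_cells = peaks, m = m, m_est = m_est,
    significance = signif, converged = converged, shape = shp, kc_px = kc,
    settings = list(r_inner_frac = r_inner_frac, r_outer_frac = r_outer_frac,
                    sigma = sigma, min_significance = min_significance,
                    refine = refine)
  ), class = "sim_fit")
}

# Bilinear lookup of |OTF| at frequency k = c(kx, ky) cycles/px.
otf_value_at <- function(otf, k) {
  v <- otf$values
  x <- k[1L] * ncol(v) + dc_index(ncol(v))
  y <- k[2L] * nrow(v) + dc_index(nrow(v))
  bilinear_at(v, x, y)
}

bilinear_at <- function(v, x, y) {
  if (x < 1 || x > ncol(v) || y < 1 || y > nrow(v)) return(0)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, ncol(v)); y1 <- min(y0 + 1, nrow(v))
  fx <- x - x0; fy <- y - y0
  v[y0, x0] * (1 - fx) * (1 - fy) + v[y0, x1] * fx * (1 - fy) +
    v[y1, x0] * (1 - fx) * fy + v[y1, x1] * fx * fy
}

#' Extract estimated illumination parameters
#'
#' @param object a `sim_fit`.
#' @param ... unused.
#' @return Named numeric vector: per-orientation angles (deg) and frequency
#'   magnitudes (cycles/px), and the 9 phases (deg).
#' @export
coef.sim_fit <- function(object, ...) {
  mag <- sqrt(rowSums(object$k_theta^2))
  out <- c(object$orientation_deg, mag, object$phases_rad * 180 / pi)
  names(out) <- c(paste0("theta", 1:3, "_deg"), paste0("kmag", 1:3),
                  paste0("phi", 1:9, "_deg"))
  out
}

#' @export
print.sim_fit <- function(x, ...) {
  cat("SIM illumination parameter estimate\n")
  for (o in 1:3) {
    ph <- x$phases_rad[3L * (o - 1L) + 1:3] * 180 / pi
    cat(sprintf(
      "  orientation %d: theta = %7.2f deg, |k| = %.5f cycles/px (%.2f, %.2f cells), phases = %s deg\n",
      o, x$orientation_deg[o], sqrt(sum(x$k_theta[o, ]^2)),
      x$k_cells[o, 1L], x$k_cells[o, 2L],
      paste(sprintf("%.2f", ph), collapse = ", ")))
  }
  cat(sprintf("  m (assumed) = %g; m_est = %s; peak significance = %s\n",
              x$m, paste(sprintf("%.2f", x$m_est), collapse = ", "),
              paste(sprintf("%.0f", x$significance), collapse = ", ")))
  invisible(x)
}

#' @export
summary.sim_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  cutoff k_c = %.4f cycles/px; |k|/k_c = %s\n",
              object$kc_px,
              paste(sprintf("%.3f", sqrt(rowSums(object$k_theta^2)) / object$kc_px),
                    collapse = ", ")))
  invisible(object)
}
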
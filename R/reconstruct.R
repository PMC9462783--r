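# Band separation, sub-pixel Fourier shifting and generalized Wiener fusion.
#
# Per orientation the three phase-stepped raw spectra are a 3 x 3 linear mix
# of the 0th and +/-1st modulation orders; inverting the mixing matrix M
# separates them. The first orders are then translated back to their true
# positions in frequency space (a complex exponential ramp in real space, so
# non-integer shifts are exact), and all nine bands are fused by the
# generalized Wiener filter
#   S_SIM(k) = sum_n OTF_n(k)* R_n(k) / (sum_n |OTF_n(k)|^2 + w),
# whose inverse transform is the super-resolved image. Fusion happens on a
# 2x zero-padded frequency grid so the extended support is not clipped; the
# output image is correspondingly 2x upsampled.

#' Band-mixing matrix of one orientation
#'
#' Row `n` is `[1, (m/2) e^{i phi_n}, (m/2) e^{-i phi_n}]`; it maps the
#' column of bands (0, +1, -1 orders) to the three observed spectra.
#' Singular when two phases coincide (mod 2 pi) or `m = 0`.
#'
#' @param phases_rad the 3 illumination phases.
#' @param m modulation depth (> 0).
#' @return A `separation_matrix`: the 3 x 3 complex matrix `entries`, its
#'   inverse, the phases, `m` and the condition number.
#' @export
separation_matrix <- function(phases_rad, m) {
  if (length(phases_rad) != 3L) stop("need exactly 3 phases")
  if (m <= 0) stop("`m` must be positive")
  d <- abs(wrap_pi(outer(phases_rad, phases_rad, `-`)))
  if (any(d[upper.tri(d)] < 1e-6)) {
    stop("singular separation matrix: phases are not pairwise distinct (mod 2*pi)")
  }
  M <- cbind(1, (m / 2) * exp(1i * phases_rad), (m / 2) * exp(-1i * phases_rad))
  structure(list(entries = M, inverse = solve(M), phases_rad = phases_rad,
                 m = m, condition = kappa(M, exact = TRUE)),
            class = "separation_matrix")
}

#' @export
print.separation_matrix <- function(x, ...) {
  cat(sprintf("Band separation matrix: phases %s deg, m = %g, condition %.3g\n",
              paste(sprintf("%.1f", x$phases_rad * 180 / pi), collapse = ", "),
              x$m, x$condition))
  invisible(x)
}

#' Separate the spectral bands of one orientation
#'
#' Applies the inverse mixing matrix pixelwise to the 3 centered raw spectra,
#' returning the 0th-order band `S~(k) OTF(k)` and the two modulation orders
#' `S~(k -/+ k_theta) OTF(k)` (scaled by the mean illumination intensity).
#'
#' @param frame_spectra list of 3 complex centered spectra.
#' @param M a [separation_matrix()].
#' @return List `order0`, `plus`, `minus` of complex matrices.
#' @export
separate_components <- function(frame_spectra, M) {
  stopifnot(inherits(M, "separation_matrix"), length(frame_spectra) == 3L)
  shp <- dim(frame_spectra[[1L]])
  D <- rbind(as.vector(frame_spectra[[1L]]),
             as.vector(frame_spectra[[2L]]),
             as.vector(frame_spectra[[3L]]))
  B <- M$inverse %*% D
  list(order0 = matrix(B[1L, ], shp[1L], shp[2L]),
       plus = matrix(B[2L, ], shp[1L], shp[2L]),
       minus = matrix(B[3L, ], shp[1L], shp[2L]))
}

#' Translate a spectrum by a (possibly non-integer) frequency shift
#'
#' Multiplies the real-space inverse transform by the complex exponential
#' ramp `exp(+2i pi v . r)` and re-transforms, translating the spectrum
#' content by `+v` exactly (an integer `v` equals a circular roll of the
#' spectrum).
#'
#' @param band_spectrum complex centered spectrum.
#' @param shift_cycles shift `c(kx, ky)` in cycles/px of the band's own grid.
#' @param pixel_scale physical size of this grid's pixel relative to the
#'   reference pixel in which `shift_cycles` is expressed (0.5 on a 2x
#'   zero-padded grid).
#' @return Complex centered spectrum.
#' @export
fourier_shift <- function(band_spectrum, shift_cycles, pixel_scale = 1) {
  if (any(!is.finite(shift_cycles))) stop("shift must be finite")
  g <- coord_grids(dim(band_spectrum), scale = pixel_scale)
  ramp <- exp(2i * pi * (shift_cycles[1L] * g$x + shift_cycles[2L] * g$y))
  b <- ifft2(ifftshift2(band_spectrum))
  fftshift2(fft2(b * ramp))
}

#' Shifted OTF
#'
#' The OTF resampled at `k - shift` (bilinear interpolation between grid
#' cells, zero outside the original support): the passband of a band whose
#' content was translated by `+shift`.
#'
#' @param otf_values real matrix of OTF values (centered) or an `otf`.
#' @param shift_cells shift `c(kx, ky)` in grid cells.
#' @return Real matrix of the same shape.
#' @export
shifted_otf <- function(otf_values, shift_cells) {
  v <- if (inherits(otf_values, "otf")) otf_values$values else otf_values
  nr <- nrow(v); nc <- ncol(v)
  xs <- seq_len(nc) - shift_cells[1L]
  ys <- seq_len(nr) - shift_cells[2L]
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  colv <- function(j) if (j >= 1 && j <= nc) v[, j] else numeric(nr)
  rowpick <- function(col, i0, fyv) {
    lo <- ifelse(i0 >= 1 & i0 <= nr, col[pmin(pmax(i0, 1L), nr)], 0)
    hi <- ifelse(i0 + 1L >= 1 & i0 + 1L <= nr, col[pmin(pmax(i0 + 1L, 1L), nr)], 0)
    lo * (1 - fyv) + hi * fyv
  }
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    c_lo <- rowpick(colv(x0[j]), y0, fy)
    c_hi <- rowpick(colv(x0[j] + 1L), y0, fy)
    out[, j] <- c_lo * (1 - fx[j]) + c_hi * fx[j]
  }
  out
}

#' Generalized Wiener fusion of shifted bands
#'
#' `S_SIM(k) = sum_n OTF_n(k)* R_n(k) / (sum_n |OTF_n(k)|^2 + w)`.
#'
#' @param bands list of N complex centered spectra (already shifted).
#' @param otfs list of N real matrices (the correspondingly shifted OTFs).
#' @param w Wiener constant (> 0), relative to a DC-normalized OTF.
#' @param backend element-wise execution backend.
#' @return Complex matrix `S_SIM`.
#' @export
wiener_combine <- function(bands, otfs, w,
                           backend = getOption("stripesim.backend", "serial")) {
  if (w <= 0) stop("`w` must be positive")
  if (length(bands) < 1L || length(bands) != length(otfs)) {
    stop("`bands` and `otfs` must be equal-length, non-empty lists")
  }
  shp <- dim(bands[[1L]])
  num <- matrix(0 + 0i, shp[1L], shp[2L])
  den <- matrix(0, shp[1L], shp[2L])
  for (n in seq_along(bands)) {
    if (!identical(dim(bands[[n]]), shp) || !identical(dim(otfs[[n]]), shp)) {
      stop("band/OTF shapes disagree")
    }
    num <- elementwise("add", num,
                       elementwise("wiener_num_term", otfs[[n]], bands[[n]],
                                   backend = backend), backend = backend)
    den <- elementwise("add", den,
                       elementwise("wiener_den_term", otfs[[n]],
                                   backend = backend), backend = backend)
  }
  elementwise("ratio_reg", num, den, w, backend = backend)
}

#' Reconstruction settings
#'
#' @param w Wiener constant (default 0.1).
#' @param sigma pre-filter constant carried to parameter estimation
#'   (default 0.01).
#' @param pad_factor frequency-grid padding factor (default 2; 1 fuses on
#'   the native grid and clips the extended support).
#' @param apodization `"none"` (default, the plain generalized Wiener
#'   output) or `"triangle"` (linear taper to zero at the extended cutoff,
#'   suppressing ringing).
#' @return A `recon_config`.
#' @export
recon_config <- function(w = 0.1, sigma = 0.01, pad_factor = 2,
                         apodization = c("none", "triangle")) {
  if (w <= 0) stop("`w` must be positive")
  if (sigma <= 0) stop("`sigma` must be positive")
  if (!pad_factor %in% c(1, 2)) stop("`pad_factor` must be 1 or 2")
  structure(list(w = w, sigma = sigma, pad_factor = as.integer(pad_factor),
                 apodization = match.arg(apodization)),
            class = "recon_config")
}

#' Reconstruct a super-resolved image from a raw stack
#'
#' Full pipeline: per-orientation band separation with the estimated phases,
#' sub-pixel Fourier shift of the first-order bands back to their true
#' frequency positions, assembly of the nine shifted bands and OTFs, and
#' generalized Wiener fusion followed by an inverse transform. The result is
#' on a `pad_factor`-times finer pixel grid than the input.
#'
#' @param stack a `sim_stack` (pre-processed if desired).
#' @param estimate a `sim_fit` from [estimate_all()], or an
#'   [illumination_model()] whose true parameters should be forced (e.g. the
#'   simulator's ground truth, or nominal phases for ablation).
#' @param otf an `otf`; default: analytic OTF of the stack's optical system.
#' @param config a [recon_config()].
#' @param backend element-wise execution backend.
#' @return A `sim_reconstruction`: real `image` (pad_factor^2 x the input
#'   pixel count), complex centered `spectrum`, `effective_cutoff`
#'   (cycles/px of the input grid), `widefield` (mean of the 9 raw frames),
#'   `params_used`, `config`.
#' @export
reconstruct <- function(stack, estimate, otf = NULL, config = recon_config(),
                        backend = getOption("stripesim.backend", "serial")) {
  stopifnot(inherits(stack, "sim_stack"), inherits(config, "recon_config"))
  shp <- dim(stack$frames[[1L]])
  if (is.null(otf)) {
    sys <- stack$meta$system
    if (is.null(sys)) stop("no OTF given and the stack records no optical system")
    otf <- analytic_otf(sys, shp)
  }
  if (inherits(estimate, "illumination_model")) {
    estimate <- fit_from_model(estimate, shp, otf$kc_px)
  }
  stopifnot(inherits(estimate, "sim_fit"))
  pad <- config$pad_factor
  pshape <- pad * shp
  scale <- 1 / pad
  otf_pad <- Re(embed_centered(otf$values, pshape))
  bands <- vector("list", 9L)
  otfs <- vector("list", 9L)
  for (o in 1:3) {
    idx <- 3L * (o - 1L) + 1:3
    spectra <- tryCatch(
      lapply(stack$frames[idx], function(f) fftshift2(fft2(f))),
      error = function(e) stop(sprintf("transform stage, orientation %d: %s",
                                       o, conditionMessage(e)), call. = FALSE))
    M <- tryCatch(
      separation_matrix(estimate$phases_rad[idx], estimate$m),
      error = function(e) stop(sprintf("separation stage, orientation %d: %s",
                                       o, conditionMessage(e)), call. = FALSE))
    sep <- separate_components(spectra, M)
    k <- estimate$k_theta[o, ]
    cells <- c(k[1L] * shp[2L], k[2L] * shp[1L])
    b0 <- embed_centered(sep$order0, pshape)
    bp <- fourier_shift(embed_centered(sep$plus, pshape), -k, pixel_scale = scale)
    bm <- fourier_shift(embed_centered(sep$minus, pshape), +k, pixel_scale = scale)
    bands[[idx[1L]]] <- b0
    bands[[idx[2L]]] <- bp
    bands[[idx[3L]]] <- bm
    otfs[[idx[1L]]] <- otf_pad
    otfs[[idx[2L]]] <- shifted_otf(otf_pad, -cells)
    otfs[[idx[3L]]] <- shifted_otf(otf_pad, +cells)
  }
  s_sim <- wiener_combine(bands, otfs, config$w, backend = backend)
  kmax <- max(sqrt(rowSums(estimate$k_theta^2)))
  eff_cut <- otf$kc_px + kmax
  if (config$apodization == "triangle") {
    r <- freq_radius(pshape) / scale  # cycles per input px
    apo <- pmax(0, 1 - r / eff_cut)
    dim(apo) <- pshape
    s_sim <- s_sim * apo
  }
  img_c <- ifft2(ifftshift2(s_sim))
  image <- Re(img_c) * pad^2
  widefield <- Reduce(`+`, stack$frames) / 9
  structure(list(image = image, spectrum = s_sim,
                 effective_cutoff = eff_cut, kc_px = otf$kc_px,
                 max_imag_residual = max(Mod(Im(img_c))) /
                   max(Mod(img_c), .Machine$double.xmin),
                 widefield = widefield, params_used = estimate,
                 config = config, input_shape = shp),
            class = "sim_reconstruction")
}

# Wrap a (true or nominal) illumination model as a sim_fit so reconstruct()
# can be forced to use known parameters.
fit_from_model <- function(model, shape, kc_px) {
  k_cells <- cbind(model$k_theta[, 1L] * shape[2L],
                   model$k_theta[, 2L] * shape[1L])
  structure(list(
    k_theta = model$k_theta, k_cells = k_cells,
    orientation_deg = atan2(model$k_theta[, 2L], model$k_theta[, 1L]) * 180 / pi,
    phases_rad = wrap_pi(model$phases_rad),
    peaks_cells = matrix(round(k_cells[rep(1:3, each = 3L), ]), 9L, 2L),
    m = model$m, m_est = rep(NA_real_, 3L), significance = rep(NA_real_, 3L),
    converged = rep(TRUE, 3L), shape = shape, kc_px = kc_px,
    settings = list(forced = TRUE)
  ), class = "sim_fit")
}

#' @export
print.sim_reconstruction <- function(x, ...) {
  cat(sprintf("SIM reconstruction: %d x %d image (input %d x %d)\n",
              nrow(x$image), ncol(x$image), x$input_shape[1L], x$input_shape[2L]))
  cat(sprintf("  effective cutoff %.4f cycles/px (widefield %.4f): support extended %.2fx\n",
              x$effective_cutoff, x$kc_px, x$effective_cutoff / x$kc_px))
  cat(sprintf("  Wiener w = %g, apodization = %s, imaginary residual %.2e\n",
              x$config$w, x$config$apodization, x$max_imag_residual))
  invisible(x)
}

#' Display a reconstruction next to its widefield reference
#'
#' @param x a `sim_reconstruction`.
#' @param which `"images"` (widefield vs reconstruction) or `"spectra"`
#'   (log-magnitude spectra).
#' @param ... passed to [graphics::image()].
#' @export
plot.sim_reconstruction <- function(x, which = c("images", "spectra"), ...) {
  which <- match.arg(which)
  op <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(par(op), add = TRUE)
  show <- function(m, main) {
    image(t(m)[, nrow(m):1], col = gray(seq(0, 1, length.out = 256)),
          axes = FALSE, main = main, useRaster = TRUE, ...)
  }
  if (which == "images") {
    show(x$widefield, "widefield")
    show(x$image, "SIM reconstruction")
  } else {
    wf <- fftshift2(fft2(x$widefield))
    show(log1p(Mod(wf)), "widefield spectrum")
    show(log1p(Mod(x$spectrum)), "SIM spectrum")
  }
  invisible(x)
}
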
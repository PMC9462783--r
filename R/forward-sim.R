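# Forward image-formation simulator.
#
# Detector model: D(r) = [I(r) * S(r)] (x) PSF(r) with sinusoidal stripe
# illumination I(r) = I0 * (1 + m cos(2 pi k_theta . r + phi)). In frequency
# space each raw frame mixes the sample spectrum with two copies shifted by
# -/+ k_theta, weighted (m/2) e^{+/- i phi}, all attenuated by the OTF; that
# band structure is what the reconstruction inverts. Convolution is circular
# (FFT-based), consistent with the Fourier processing downstream. Illumination
# frequencies are specified in continuous cycles/px and evaluated in real
# space, so off-grid frequencies are represented exactly (needed to exercise
# sub-pixel frequency estimation).

#' Synthetic fluorophore density maps
#'
#' Deterministic given `seed`. Kinds:
#' \describe{
#'   \item{beads}{`n` single-pixel unit impulses at uniform positions (true
#'     point emitters; default `n = 50`).}
#'   \item{spokes}{a Siemens-star radial target (`n_spokes` cosine spokes,
#'     default 36, inside a disk of radius `0.45 * min(shape)`), values in
#'     \[0, 1\].}
#'   \item{filaments}{`n` random-walk curves of 1 px width (default 12 walks
#'     of length `4 * min(shape)` steps), clipped to \[0, 1\].}
#'   \item{custom}{caller-supplied matrix via `values`.}
#' }
#' Any kind accepts `blur_sigma` (px): a Gaussian low-pass applied to the
#' map, producing a spectrally band-limited sample (useful when a smooth
#' ground truth is wanted, e.g. for parameter-recovery studies where sample
#' frequency content near twice the illumination frequency would leak into
#' phase estimates).
#'
#' @param kind one of `"beads"`, `"spokes"`, `"filaments"`, `"custom"`.
#' @param shape grid size `c(rows, cols)`, at least 64 x 64.
#' @param seed RNG seed (integer).
#' @param ... kind parameters: `n`, `n_spokes`, `values`, `blur_sigma`,
#'   `margin`.
#' @return A `ground_truth`: list with non-negative matrix `values`, `kind`
#'   and `seed`; for beads also `centers` (n x 2, 1-based `x`/`y` pixel
#'   positions, recorded before any blur).
#' @export
make_ground_truth <- function(kind = c("beads", "spokes", "filaments", "custom"),
                              shape = c(512L, 512L), seed = 1L, ...) {
  kind <- match.arg(kind)
  if (any(shape < 64)) stop("`shape` must be at least 64 x 64")
  dots <- list(...)
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  values <- switch(kind,
    beads = {
      n <- dots$n %||% 50L
      margin <- dots$margin %||% 8L
      room <- min(nr, nc) - 2L * margin
      if (n > room) {
        stop(sprintf(
          "cannot place %d beads: only %d distinct rows/columns inside the %d px margin",
          n, room, margin))
      }
      v <- matrix(0, nr, nc)
      rows <- sample(seq.int(margin + 1L, nr - margin), n, replace = FALSE)
      cols <- sample(seq.int(margin + 1L, nc - margin), n, replace = FALSE)
      v[cbind(rows, cols)] <- 1
      attr(v, "centers") <- cbind(x = cols, y = rows)
      v
    },
    spokes = {
      n_spokes <- dots$n_spokes %||% 36L
      g <- coord_grids(c(nr, nc))
      cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
      ang <- atan2(g$y - cy, g$x - cx)
      rad <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
      v <- 0.5 * (1 + cos(n_spokes * ang))
      v[rad > 0.45 * min(nr, nc) | rad < 4] <- 0
      v
    },
    filaments = {
      n <- dots$n %||% 12L
      steps <- dots$steps %||% (4L * min(nr, nc))
      v <- matrix(0, nr, nc)
      for (f in seq_len(n)) {
        x <- runif(1, 1, nc); y <- runif(1, 1, nr)
        heading <- runif(1, 0, 2 * pi)
        for (s in seq_len(steps)) {
          heading <- heading + rnorm(1, 0, 0.15)
          x <- x + cos(heading); y <- y + sin(heading)
          # wrap around the torus so walks stay on the grid
          x <- ((x - 1) %% nc) + 1; y <- ((y - 1) %% nr) + 1
          v[((round(y) - 1L) %% nr) + 1L, ((round(x) - 1L) %% nc) + 1L] <- 1
        }
      }
      v
    },
    custom = {
      v <- dots$values
      if (is.null(v) || !is.matrix(v)) stop("kind 'custom' requires a `values` matrix")
      if (any(v < 0) || any(!is.finite(v))) stop("ground truth must be finite and non-negative")
      v
    }
  )
  centers <- attr(values, "centers")
  attr(values, "centers") <- NULL
  if (!is.null(dots$blur_sigma) && dots$blur_sigma > 0) {
    values <- gaussian_blur(values, dots$blur_sigma)
    values[values < 0] <- 0
  }
  structure(list(values = values, kind = kind, seed = as.integer(seed),
                 centers = centers),
            class = "ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular Gaussian blur
#'
#' FFT-based convolution with an isotropic Gaussian (frequency response
#' `exp(-2 pi^2 sigma^2 |k|^2)`); boundaries wrap.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in px.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  h <- exp(-(freq_radius(dim(x))^2) * 2 * pi^2 * sigma^2)
  Re(ifft2(fft2(x) * ifftshift2(h)))
}

# Save/restore .Random.seed so generator calls do not perturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sinusoidal illumination model
#'
#' Bundles the per-orientation frequency vectors, the 9 per-frame phases, the
#' modulation depth and the mean intensity. `default_illumination` builds the
#' standard three-orientation geometry: orientations 0, 60, 120 degrees,
#' phases 0, 120, 240 degrees within each orientation, and `|k_theta| =
#' ktheta_frac * k_c`.
#'
#' @param k_theta 3 x 2 matrix of frequency vectors `(kx, ky)` in cycles/px,
#'   one row per orientation.
#' @param phases_rad 9 per-frame phases (orientation-major).
#' @param m modulation depth in \[0, 1\].
#' @param i0 mean illumination intensity (> 0).
#' @return An `illumination_model`.
#' @export
illumination_model <- function(k_theta, phases_rad, m = 0.8, i0 = 1) {
  k_theta <- matrix(as.numeric(k_theta), ncol = 2L)
  if (nrow(k_theta) != 3L) stop("`k_theta` must give 3 orientation frequency vectors")
  if (length(phases_rad) != 9L) stop("`phases_rad` must have length 9")
  if (m < 0 || m > 1) stop("`m` must be in [0, 1]")
  if (i0 <= 0) stop("`i0` must be positive")
  structure(list(k_theta = k_theta, phases_rad = as.numeric(phases_rad),
                 m = m, i0 = i0), class = "illumination_model")
}

#' @rdname illumination_model
#' @param system an [optical_system()].
#' @param orientations_deg 3 stripe orientations in degrees.
#' @param ktheta_frac illumination frequency magnitude as a fraction of the
#'   cutoff `k_c` (default 0.8).
#' @param phases_rad_one 3 phases applied within each orientation.
#' @export
default_illumination <- function(system, orientations_deg = c(0, 60, 120),
                                 ktheta_frac = 0.8,
                                 phases_rad_one = c(0, 2 * pi / 3, 4 * pi / 3),
                                 m = 0.8, i0 = 1) {
  stopifnot(inherits(system, "optical_system"))
  if (length(orientations_deg) != 3L) stop("need exactly 3 orientations")
  if (length(phases_rad_one) != 3L) stop("need exactly 3 phases")
  th <- orientations_deg * pi / 180
  k <- ktheta_frac * system$kc_px * cbind(cos(th), sin(th))
  illumination_model(k, rep(phases_rad_one, times = 3L), m = m, i0 = i0)
}

#' Evaluate the illumination field of one frame
#'
#' `I(r) = i0 * (1 + m * cos(2*pi * k_theta . r + phi))` with the frame's
#' orientation frequency and phase; values lie in
#' `[i0*(1-m), i0*(1+m)]`.
#'
#' @param model an [illumination_model()].
#' @param frame_index frame number 1..9 (orientation-major).
#' @param shape grid `c(rows, cols)`.
#' @return A real matrix.
#' @export
illumination_field <- function(model, frame_index, shape) {
  stopifnot(inherits(model, "illumination_model"))
  if (frame_index < 1 || frame_index > 9) stop("`frame_index` must be in 1..9")
  o <- (frame_index - 1L) %/% 3L + 1L
  k <- model$k_theta[o, ]
  phi <- model$phases_rad[frame_index]
  g <- coord_grids(shape)
  model$i0 * (1 + model$m * cos(2 * pi * (k[1L] * g$x + k[2L] * g$y) + phi))
}

#' Camera noise settings
#'
#' Shot noise is Poisson at a peak photon budget; read noise is additive
#' Gaussian in camera counts (DN) at the photon scale:
#' `D = (Poisson(g * photons) + N(0, sigma_read)) / photons` for noiseless
#' intensity `g`.
#'
#' @param photons photon count corresponding to intensity 1 (default 500).
#' @param sigma_read read-noise standard deviation in DN (default 2).
#' @return A `sim_noise` settings object.
#' @export
sim_noise <- function(photons = 500, sigma_read = 2) {
  if (photons <= 0) stop("`photons` must be positive")
  if (sigma_read < 0) stop("`sigma_read` must be non-negative")
  structure(list(photons = photons, sigma_read = sigma_read),
            class = "sim_noise")
}

#' Simulate one raw SIM frame
#'
#' Noiseless detector image `(I * S) (x) PSF` (circular convolution through
#' the OTF), optionally degraded by Poisson shot noise and Gaussian read
#' noise per [sim_noise()]. With `noise = NULL` the noiseless model is
#' returned exactly.
#'
#' @param truth a [make_ground_truth()] result.
#' @param system an [optical_system()].
#' @param model an [illumination_model()].
#' @param frame_index frame number 1..9.
#' @param noise `NULL` (noiseless) or a [sim_noise()].
#' @param otf optional precomputed [analytic_otf()] for the system/shape.
#' @return A real matrix.
#' @export
simulate_frame <- function(truth, system, model, frame_index, noise = NULL,
                           otf = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(otf)) otf <- analytic_otf(system, dim(truth$values))
  if (!identical(dim(otf$values), dim(truth$values))) {
    stop("OTF and ground-truth shapes disagree")
  }
  em <- illumination_field(model, frame_index, dim(truth$values)) * truth$values
  g <- Re(ifft2(fft2(em) * ifftshift2(otf$values)))
  if (is.null(noise)) return(g)
  stopifnot(inherits(noise, "sim_noise"))
  g[g < 0] <- 0
  counts <- rpois(length(g), g * noise$photons) +
    rnorm(length(g), 0, noise$sigma_read)
  d <- matrix(counts / noise$photons, nrow(g), ncol(g))
  d[d < 0] <- 0
  d
}

#' Simulate a full 9-frame raw stack
#'
#' Frames are orientation-major, phase-minor. The metadata records the true
#' illumination model so estimators can be validated against ground truth.
#'
#' @inheritParams simulate_frame
#' @param seed seed controlling all randomness (frame noise).
#' @return A `sim_stack`: list of 9 frames plus `meta` (system, true model,
#'   noise settings, seed).
#' @export
simulate_stack <- function(truth, system, model = NULL, noise = NULL,
                           seed = 1L) {
  if (is.null(model)) model <- default_illumination(system)
  otf <- analytic_otf(system, dim(truth$values))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  frames <- lapply(1:9, function(n) {
    simulate_frame(truth, system, model, n, noise = noise, otf = otf)
  })
  sim_stack(frames, meta = list(system = system, model = model, noise = noise,
                                seed = as.integer(seed),
                                truth_kind = truth$kind))
}

#' Widefield (uniform illumination) reference image
#'
#' The acquisition made with all DMD mirrors on: [simulate_frame()] with
#' modulation depth 0.
#'
#' @inheritParams simulate_stack
#' @return A real matrix.
#' @export
widefield_reference <- function(truth, system, noise = NULL, seed = 1L) {
  model <- illumination_model(matrix(0, 3, 2), rep(0, 9), m = 0, i0 = 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  simulate_frame(truth, system, model, 1L, noise = noise)
}

#' Construct / validate a raw stack
#'
#' @param frames list of exactly 9 equal-shape non-negative finite matrices,
#'   orientation-major.
#' @param meta metadata list (optical system, nominal illumination, noise,
#'   seed) or `NULL`.
#' @return A `sim_stack`.
#' @export
sim_stack <- function(frames, meta = NULL) {
  if (!is.list(frames) || length(frames) != 9L) {
    stop(sprintf("a raw SIM stack needs exactly 9 frames, got %d",
                 length(frames)))
  }
  shp <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), shp)) stop("frames have mixed shapes")
    if (any(!is.finite(f))) stop("frames must be finite")
    # allow the ~1e-16-scale negative ringing of exact band-limited frames
    if (any(f < -1e-9 * max(abs(f), 1e-12))) stop("frames must be non-negative")
  }
  structure(list(frames = frames, meta = meta), class = "sim_stack")
}

#' @export
print.sim_stack <- function(x, ...) {
  shp <- dim(x$frames[[1L]])
  cat(sprintf("SIM raw stack: 9 frames of %d x %d (orientation-major)\n",
              shp[1L], shp[2L]))
  if (!is.null(x$meta$model)) {
    a <- atan2(x$meta$model$k_theta[, 2L], x$meta$model$k_theta[, 1L]) * 180 / pi
    cat(sprintf("  nominal orientations: %s deg, m = %g\n",
                paste(sprintf("%.1f", a), collapse = ", "), x$meta$model$m))
  }
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth '%s': %d x %d, seed %d, %d nonzero px\n",
              x$kind, nrow(x$values), ncol(x$values), x$seed,
              sum(x$values > 0)))
  invisible(x)
}
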
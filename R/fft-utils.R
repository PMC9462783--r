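# Fourier helpers shared by the optics, simulation, estimation and
# reconstruction code. All user-facing spectra are centered (DC at
# floor(n/2)+1 per axis); fftshift2/ifftshift2 convert between centered and
# corner (FFT-native) layout.

#' Two-dimensional FFT helpers
#'
#' Thin wrappers around [stats::fft()] plus the quadrant swaps used to move
#' the DC bin between the array corner (FFT-native) and the grid center
#' (user-facing). `fft2` and `ifft2` operate on corner-form arrays; `ifft2`
#' includes the `1/(nrow*ncol)` normalization.
#'
#' @param x numeric or complex matrix.
#' @return A complex (or same-type, for the shifts) matrix of the same shape.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' max(Mod(ifft2(fft2(x)) - x)) < 1e-12
#' @export
fft2 <- function(x) stats::fft(x)

#' @rdname fft2
#' @export
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @rdname fft2
#' @export
fftshift2 <- function(x) {
  stopifnot(is.matrix(x))
  ir <- ((seq_len(nrow(x)) - 1L - nrow(x) %/% 2L) %% nrow(x)) + 1L
  ic <- ((seq_len(ncol(x)) - 1L - ncol(x) %/% 2L) %% ncol(x)) + 1L
  x[ir, ic, drop = FALSE]
}

#' @rdname fft2
#' @export
ifftshift2 <- function(x) {
  stopifnot(is.matrix(x))
  ir <- ((seq_len(nrow(x)) - 1L + nrow(x) %/% 2L) %% nrow(x)) + 1L
  ic <- ((seq_len(ncol(x)) - 1L + ncol(x) %/% 2L) %% ncol(x)) + 1L
  x[ir, ic, drop = FALSE]
}

#' Centered frequency-grid geometry
#'
#' `dc_index(n)` is the 1-based index of the DC bin on a centered axis of
#' length `n` (`floor(n/2) + 1`); `freq_axis(n)` the centered frequency axis
#' in cycles/px; `freq_radius(shape)` the centered `|k|` grid.
#'
#' @param n axis length.
#' @param shape grid `c(rows, cols)`.
#' @return Integer index, numeric vector, or numeric matrix respectively.
#' @export
dc_index <- function(n) n %/% 2L + 1L

#' @rdname dc_index
#' @export
freq_axis <- function(n) (seq_len(n) - 1L - n %/% 2L) / n

#' @rdname dc_index
#' @export
freq_radius <- function(shape) {
  fy <- freq_axis(shape[1L])
  fx <- freq_axis(shape[2L])
  sqrt(outer(fy^2, fx^2, `+`))
}

# Pixel coordinate grids: X[r, c] = c - 1, Y[r, c] = r - 1, optionally scaled
# (scale < 1 for upsampled grids whose pixels subtend a fraction of the
# original pixel).
coord_grids <- function(shape, scale = 1) {
  list(
    x = matrix(rep((seq_len(shape[2L]) - 1) * scale, each = shape[1L]),
               shape[1L], shape[2L]),
    y = matrix(rep((seq_len(shape[1L]) - 1) * scale, times = shape[2L]),
               shape[1L], shape[2L])
  )
}

#' Discrete-time Fourier transform at arbitrary frequencies
#'
#' `dtft_point` evaluates `sum_{x,y} d[y,x] exp(-2i pi (kx x + ky y))` at one
#' frequency `k = c(kx, ky)` (cycles/px, x = col - 1, y = row - 1);
#' `dtft_zoom` evaluates it on the rectangular window `ky` x `kx` via matrix
#' products (the zoomed spectrum used for sub-pixel peak location).
#'
#' @param d numeric or complex matrix.
#' @param k frequency `c(kx, ky)` in cycles/px.
#' @param kx,ky frequency vectors in cycles/px.
#' @return A complex scalar (`dtft_point`) or `length(ky)` x `length(kx)`
#'   complex matrix (`dtft_zoom`).
#' @export
dtft_point <- function(d, k) {
  ex <- exp(-2i * pi * k[1L] * (seq_len(ncol(d)) - 1))
  ey <- exp(-2i * pi * k[2L] * (seq_len(nrow(d)) - 1))
  drop(crossprod(ey, d %*% ex))
}

#' @rdname dtft_point
#' @export
dtft_zoom <- function(d, kx, ky) {
  Ex <- exp(-2i * pi * outer(seq_len(ncol(d)) - 1, kx))
  Ey <- exp(-2i * pi * outer(ky, seq_len(nrow(d)) - 1))
  Ey %*% d %*% Ex
}

#' Embed a centered spectrum in a larger zero grid
#'
#' Frequency zero-padding: the bin spacing in cycles per *original* pixel is
#' unchanged, the covered frequency range grows by the shape ratio (and the
#' inverse transform's pixels shrink by it).
#'
#' @param x complex centered matrix.
#' @param shape target `c(rows, cols)`, at least `dim(x)`.
#' @return Complex matrix of size `shape` with `x` centered on its DC bin.
#' @export
embed_centered <- function(x, shape) {
  out <- matrix(0 + 0i, shape[1L], shape[2L])
  r0 <- dc_index(shape[1L]) - dc_index(nrow(x))
  c0 <- dc_index(shape[2L]) - dc_index(ncol(x))
  out[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))] <- x
  out
}

#' Wrap angles to (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return Angles congruent to `a` modulo `2*pi`, in `(-pi, pi]`.
#' @export
wrap_pi <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}
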
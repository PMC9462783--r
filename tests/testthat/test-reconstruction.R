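test_that("separation matrix inverts exactly for equispaced phases", {
  M <- separation_matrix(c(0, 2 * pi / 3, 4 * pi / 3), 0.8)
  expect_equal(M$entries %*% M$inverse, diag(3) + 0i, tolerance = 1e-13)
  # rows are [1, (m/2) e^{i phi}, (m/2) e^{-i phi}]
  expect_equal(M$entries[2L, ], c(1, 0.4 * exp(1i * 2 * pi / 3),
                                 0.4 * exp(-1i * 2 * pi / 3)), tolerance = 1e-14)
  expect_error(separation_matrix(c(0, 0, 2), 0.8), "phases")
  expect_error(separation_matrix(c(0, 2, 4), 0))
})

test_that("separate_components inverts a hand-assembled band mixture", {
  shp <- c(32L, 32L)
  set.seed(5)
  rnd <- function() matrix(complex(real = rnorm(prod(shp)),
                                   imaginary = rnorm(prod(shp))),
                           shp[1L], shp[2L])
  b0 <- rnd(); bp <- rnd(); bm <- rnd()
  phases <- c(0.3, 0.3 + 2 * pi / 3, 0.3 + 4 * pi / 3)
  m <- 0.7
  spectra <- lapply(phases, function(phi) {
    b0 + (m / 2) * exp(1i * phi) * bp + (m / 2) * exp(-1i * phi) * bm
  })
  M <- separation_matrix(phases, m)
  out <- separate_components(spectra, M)
  expect_equal(out$order0, b0, tolerance = 1e-12)
  expect_equal(out$plus, bp, tolerance = 1e-12)
  expect_equal(out$minus, bm, tolerance = 1e-12)
})

test_that("fourier_shift translates spectra exactly", {
  shp <- c(32L, 32L)
  set.seed(6)
  spec <- matrix(complex(real = rnorm(prod(shp)), imaginary = rnorm(prod(shp))),
                 shp[1L], shp[2L])
  # integer shifts equal a circular roll of the centered spectrum
  v <- c(3L, -5L)
  rolled <- spec[((seq_len(32) - 1 - v[2L]) %% 32) + 1,
                 ((seq_len(32) - 1 - v[1L]) %% 32) + 1]
  expect_equal(fourier_shift(spec, v / 32), rolled, tolerance = 1e-10)
  # shift then unshift is the identity (criterion-6 oracle lives in
  # test-acceptance; this covers the non-integer + pixel_scale case)
  w <- c(0.173, -0.081)
  back <- fourier_shift(fourier_shift(spec, w, 0.5), -w, 0.5)
  expect_lt(max(Mod(back - spec)), 1e-9)
})

test_that("shifted_otf resamples with zero fill outside the support", {
  otf <- default_otf(c(64L, 64L))
  # integer shift: exact matrix translation
  sh <- shifted_otf(otf$values, c(10L, -4L))
  expect_equal(sh[30L, 50L], otf$values[30L + 4L, 50L - 10L], tolerance = 1e-14)
  expect_equal(sh[1L, 1L], 0)  # source outside the grid
  # shift by zero is the identity
  expect_equal(shifted_otf(otf$values, c(0, 0)), otf$values, tolerance = 1e-14)
  # fractional shift stays within the convex hull of neighbours
  shf <- shifted_otf(otf$values, c(0.5, 0))
  expect_true(all(shf >= pmin(sh * 0, 0)))
  expect_lte(max(shf), max(otf$values))
})

test_that("wiener_combine implements the generalized Wiener formula", {
  shp <- c(16L, 16L)
  set.seed(7)
  bands <- replicate(3, matrix(complex(real = rnorm(256),
                                       imaginary = rnorm(256)), 16, 16),
                     simplify = FALSE)
  otfs <- replicate(3, matrix(runif(256), 16, 16), simplify = FALSE)
  w <- 0.2
  got <- wiener_combine(bands, otfs, w)
  num <- Reduce(`+`, Map(function(o, b) Conj(o) * b, otfs, bands))
  den <- Reduce(`+`, lapply(otfs, function(o) Mod(o)^2))
  expect_equal(got, num / (den + w), tolerance = 1e-12)
  expect_error(wiener_combine(bands, otfs, 0))
})

test_that("reconstruct produces a doubled real grid with extended support", {
  shp <- c(128L, 128L)
  stack <- bead_stack(shp, seed = 4)
  otf <- default_otf(shp)
  est <- estimate_all(stack, otf)
  recon <- reconstruct(stack, est, otf)
  expect_s3_class(recon, "sim_reconstruction")
  expect_equal(dim(recon$image), 2L * shp)
  expect_true(is.numeric(recon$image))
  expect_equal(dim(recon$widefield), shp)
  expect_lt(recon$max_imag_residual, 1e-6)
  expect_equal(recon$effective_cutoff,
               otf$kc_px + max(sqrt(rowSums(est$k_theta^2))), tolerance = 1e-9)
  expect_output(print(recon), "reconstruction")
})

test_that("reconstruction sharpens the image relative to widefield", {
  # point sources (flat spectra), so the support is limited by the optics
  # rather than by the sample; reconstruct with the true parameters
  shp <- c(128L, 128L)
  sys <- default_sys(shp)
  otf <- default_otf(shp)
  truth <- make_ground_truth("beads", shp, seed = 4, n = 40L, margin = 12L)
  stack <- simulate_stack(truth, sys, seed = 4)
  recon <- reconstruct(stack, stack$meta$model, otf)
  # spectral support (in cycles per *input* pixel) must grow
  s_wf <- spectral_support_radius(recon$widefield, 0.01)
  s_sim <- 2 * spectral_support_radius(recon$image, 0.01)
  expect_gt(s_sim, s_wf + 0.5 * 0.8 * otf$kc_px)
})

test_that("reconstruct validates inputs and names failing stages", {
  shp <- c(128L, 128L)
  stack <- bead_stack(shp, seed = 4)
  otf <- default_otf(shp)
  est <- estimate_all(stack, otf)
  bad <- est
  bad$phases_rad[1:3] <- 0  # duplicate phases break separation
  expect_error(reconstruct(stack, bad, otf), "separation")
  expect_error(recon_config(w = -1))
  expect_error(recon_config(pad_factor = 0))
  expect_error(recon_config(apodization = "bogus"))
})
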
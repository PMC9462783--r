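test_that("bandpass_mask selects the annulus and never the DC bin", {
  m <- bandpass_mask(c(64L, 64L), 0.1, 0.3)
  expect_true(all(m %in% c(0L, 1L)))
  expect_identical(m[dc_index(64L), dc_index(64L)], 0L)
  r <- freq_radius(c(64L, 64L))
  expect_true(all(r[m == 1L] >= 0.1 - 1e-12))
  expect_true(all(r[m == 1L] <= 0.3 + 1e-12))
  inside <- r >= 0.12 & r <= 0.28
  expect_true(all(m[inside] == 1L))
  expect_error(bandpass_mask(c(64L, 64L), 0.3, 0.1))
  expect_error(bandpass_mask(c(64L, 64L), 0, 0.3))
})

test_that("wiener_prefilter implements conj(OTF) D / (|OTF| + sigma)", {
  otf <- default_otf(c(64L, 64L))
  set.seed(3)
  spec <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  out <- wiener_prefilter(spec, otf, sigma = 0.05)
  expect_equal(out, Conj(otf$values) * spec / (Mod(otf$values) + 0.05),
               tolerance = 1e-12)
  expect_error(wiener_prefilter(spec, otf, sigma = 0))
})

test_that("find_modulation_peak reports the planted peak, positive-kx member", {
  shp <- c(64L, 64L)
  spec <- matrix(0.01, shp[1L], shp[2L])
  mask <- bandpass_mask(shp, 0.05, 0.45)
  put <- function(s, cells, v) {
    s[dc_index(shp[1L]) + cells[2L], dc_index(shp[2L]) + cells[1L]] <- v
    s
  }
  # plant a conjugate pair; the negative-kx member is the argmax magnitude
  spec1 <- put(put(spec, c(-9L, 4L), 7), c(9L, -4L), 7)
  pk <- find_modulation_peak(spec1, mask)
  expect_identical(as.integer(pk$coord_cells), c(9L, -4L))
  expect_equal(pk$magnitude, 7)
  expect_gt(pk$significance, 100)
  # ties on kx = 0 resolve toward positive ky
  spec2 <- put(put(spec, c(0L, 6L), 3), c(0L, -6L), 3)
  pk2 <- find_modulation_peak(spec2, mask)
  expect_identical(as.integer(pk2$coord_cells), c(0L, 6L))
  # significance gate
  expect_error(find_modulation_peak(spec1, mask, min_significance = 1e6),
               "significance")
  expect_error(find_modulation_peak(matrix(0, 64, 64), mask), "zero")
})

test_that("estimate_phase is the complex argument at the peak bin", {
  shp <- c(32L, 32L)
  spec <- matrix(0 + 0i, 32, 32)
  spec[dc_index(32L) + 3L, dc_index(32L) + 5L] <- 2 * exp(1i * 0.9)
  expect_equal(estimate_phase(spec, c(5L, 3L)), 0.9, tolerance = 1e-12)
  expect_error(estimate_phase(spec, c(40L, 0L)), "outside")
  expect_error(estimate_phase(spec, c(1L, 1L)), "zero")
})

test_that("phases of a pure on-grid cosine are recovered exactly", {
  shp <- c(64L, 64L)
  g <- list(x = matrix(rep(0:63, each = 64), 64, 64),
            y = matrix(rep(0:63, times = 64), 64, 64))
  k <- c(10, -6) / 64
  phi <- 1.234
  frame <- 1 + 0.8 * cos(2 * pi * (k[1] * g$x + k[2] * g$y) + phi)
  spec <- fftshift2(fft2(frame))
  expect_equal(estimate_phase(spec, c(10L, -6L)), phi, tolerance = 1e-9)
})

test_that("refine_frequency_subpixel recovers off-grid frequencies", {
  shp <- c(128L, 128L)
  stack <- bead_stack(shp, seed = 4)
  otf <- default_otf(shp)
  model <- stack$meta$model
  for (o in 1:3) {
    fr <- stack$frames[3L * (o - 1L) + 1:3]
    k_true <- model$k_theta[o, ]
    sgn <- if (k_true[1L] < 0 || (k_true[1L] == 0 && k_true[2L] < 0)) -1 else 1
    coarse <- round(sgn * k_true * 128)
    k <- refine_frequency_subpixel(fr, coarse, otf)
    expect_true(attr(k, "converged"))
    expect_lt(max(abs(as.numeric(k) - sgn * k_true) * 128), 0.02)
  }
})

test_that("estimate_all recovers a stack's own ground truth", {
  stack <- bead_stack(c(128L, 128L), seed = 4)
  est <- estimate_all(stack, default_otf(c(128L, 128L)))
  expect_s3_class(est, "sim_fit")
  model <- stack$meta$model
  for (o in 1:3) {
    sgn <- align_sign(est$k_theta[o, ], model$k_theta[o, ])
    expect_lt(max(abs(est$k_theta[o, ] - sgn * model$k_theta[o, ]) * 128), 0.02)
    idx <- 3L * (o - 1L) + 1:3
    dphi <- wrap_pi(est$phases_rad[idx] - sgn * model$phases_rad[idx])
    expect_lt(max(abs(deg(dphi))), 0.5)
  }
  expect_equal(est$m_est, rep(model$m, 3L), tolerance = 0.02)
  expect_true(all(est$significance > 5))
  expect_true(all(est$converged))
  # S3 surface
  co <- coef(est)
  expect_length(co, 15L)
  expect_named(co)
  expect_output(print(est), "orientation")
  expect_output(summary(est), "cutoff")
})

test_that("estimate_all fails loudly when there is no modulation peak", {
  shp <- c(64L, 64L)
  sys <- default_sys(shp)
  truth <- make_ground_truth("beads", shp, seed = 1, n = 20L, blur_sigma = 2)
  flat <- widefield_reference(truth, sys)
  stack <- sim_stack(replicate(9, flat, simplify = FALSE))
  expect_error(estimate_all(stack, default_otf(shp)), "orientation 1")
})
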
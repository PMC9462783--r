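test_that("ground-truth generators are deterministic and leave the RNG alone", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  t1 <- make_ground_truth("beads", c(64L, 64L), seed = 3, n = 20L)
  t2 <- make_ground_truth("beads", c(64L, 64L), seed = 3, n = 20L)
  after <- rnorm(1)
  expect_identical(t1$values, t2$values)
  expect_identical(before, after)  # generator restored .Random.seed
})

test_that("bead maps place n unit impulses and record their centers", {
  truth <- make_ground_truth("beads", c(64L, 64L), seed = 1, n = 17L)
  expect_equal(sum(truth$values), 17)
  expect_true(all(truth$values %in% c(0, 1)))
  expect_equal(nrow(truth$centers), 17L)
  expect_true(all(truth$values[cbind(truth$centers[, "y"],
                                     truth$centers[, "x"])] == 1))
})

test_that("other ground-truth kinds and validation behave", {
  sp <- make_ground_truth("spokes", c(64L, 64L))
  expect_true(all(sp$values >= 0 & sp$values <= 1))
  fl <- make_ground_truth("filaments", c(64L, 64L), n = 3L, steps = 50L)
  expect_true(any(fl$values > 0))
  cu <- make_ground_truth("custom", c(64L, 64L), values = matrix(2, 64, 64))
  expect_equal(cu$values, matrix(2, 64, 64))
  expect_error(make_ground_truth("custom", c(64L, 64L)), "values")
  expect_error(make_ground_truth("custom", c(64L, 64L),
                                 values = matrix(-1, 64, 64)), "non-negative")
  expect_error(make_ground_truth("beads", c(32L, 32L)), "64")
  expect_error(make_ground_truth("beads", c(64L, 64L), n = 60L), "beads")
})

test_that("blur_sigma band-limits the sample", {
  sharp <- make_ground_truth("beads", c(64L, 64L), seed = 2, n = 20L)
  soft <- make_ground_truth("beads", c(64L, 64L), seed = 2, n = 20L,
                            blur_sigma = 2)
  expect_lt(spectral_support_radius(soft$values, 0.01),
            spectral_support_radius(sharp$values, 0.01))
  expect_equal(sum(soft$values), sum(sharp$values), tolerance = 1e-6)
})

test_that("illumination_field implements I0 (1 + m cos(2 pi k.r + phi))", {
  sys <- default_sys(c(64L, 64L))
  model <- default_illumination(sys, m = 0.6, i0 = 2)
  f <- illumination_field(model, 4L, c(64L, 64L))  # orientation 2, phase 1
  expect_true(all(f >= 2 * (1 - 0.6) - 1e-12 & f <= 2 * (1 + 0.6) + 1e-12))
  # direct evaluation oracle
  k <- model$k_theta[2L, ]
  x <- matrix(rep(0:63, each = 64), 64, 64)
  y <- matrix(rep(0:63, times = 64), 64, 64)
  expected <- 2 * (1 + 0.6 * cos(2 * pi * (k[1] * x + k[2] * y) +
                                   model$phases_rad[4L]))
  expect_equal(f, expected, tolerance = 1e-12)
})

test_that("a noiseless frame is [(I . S) conv PSF] exactly", {
  shp <- c(64L, 64L)
  sys <- default_sys(shp)
  otf <- default_otf(shp)
  truth <- make_ground_truth("beads", shp, seed = 5, n = 10L)
  model <- default_illumination(sys)
  fr <- simulate_frame(truth, sys, model, 7L)
  emitted <- truth$values * illumination_field(model, 7L, shp)
  expected <- Re(ifft2(fft2(emitted) * ifftshift2(otf$values)))
  expect_equal(fr, expected, tolerance = 1e-10)
})

test_that("simulate_stack yields 9 frames with faithful metadata", {
  stack <- bead_stack(c(128L, 128L), seed = 1)
  expect_s3_class(stack, "sim_stack")
  expect_length(stack$frames, 9L)
  expect_equal(dim(stack$meta$model$k_theta), c(3L, 2L))
  expect_length(stack$meta$model$phases_rad, 9L)
  # |k_theta| = 0.8 kc for the default illumination
  kc <- default_sys(c(128L, 128L))$kc_px
  expect_equal(sqrt(rowSums(stack$meta$model$k_theta^2)), rep(0.8 * kc, 3L),
               tolerance = 1e-12)
})

test_that("noise is reproducible by seed and respects the photon budget", {
  shp <- c(64L, 64L)
  sys <- default_sys(shp)
  truth <- make_ground_truth("beads", shp, seed = 2, n = 20L, blur_sigma = 1)
  noise <- sim_noise(photons = 200, sigma_read = 1)
  s1 <- simulate_stack(truth, sys, noise = noise, seed = 42)
  s2 <- simulate_stack(truth, sys, noise = noise, seed = 42)
  s3 <- simulate_stack(truth, sys, noise = noise, seed = 43)
  expect_identical(s1$frames, s2$frames)
  expect_false(identical(s1$frames, s3$frames))
  expect_true(all(vapply(s1$frames, function(f) all(f >= 0), logical(1L))))
})

test_that("widefield_reference equals the m = 0 forward model", {
  shp <- c(64L, 64L)
  sys <- default_sys(shp)
  truth <- make_ground_truth("beads", shp, seed = 2, n = 20L)
  wf <- widefield_reference(truth, sys)
  otf <- default_otf(shp)
  expected <- Re(ifft2(fft2(truth$values) * ifftshift2(otf$values)))
  expect_equal(wf, expected, tolerance = 1e-10)
})

test_that("sim_stack validates frame count and values", {
  f <- replicate(8, matrix(1, 8, 8), simplify = FALSE)
  expect_error(sim_stack(f), "9")
  f9 <- replicate(9, matrix(1, 8, 8), simplify = FALSE)
  expect_s3_class(sim_stack(f9), "sim_stack")
  f9[[3L]] <- matrix(-1, 8, 8)
  expect_error(sim_stack(f9))
  f9[[3L]] <- matrix(1, 9, 8)
  expect_error(sim_stack(f9))
})
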
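test_that("pixel_shift_for_phase gives exact integer shifts where they exist", {
  s <- pixel_shift_for_phase(6, 2 * pi / 3)
  expect_identical(as.integer(s), 2L)
  expect_true(attr(s, "exact"))
  expect_equal(attr(s, "realized_phase_rad"), 2 * pi / 3, tolerance = 1e-12)

  s9 <- pixel_shift_for_phase(9, 2 * pi / 3)
  expect_identical(as.integer(s9), 3L)
  expect_true(attr(s9, "exact"))

  expect_identical(as.integer(pixel_shift_for_phase(6, 0)), 0L)
  expect_identical(as.integer(pixel_shift_for_phase(6, 4 * pi / 3)), 4L)
})

test_that("pixel_shift_for_phase rounds and warns for non-integer shifts", {
  expect_warning(s <- pixel_shift_for_phase(5, 2 * pi / 3), "rounding")
  expect_false(attr(s, "exact"))
  expect_identical(as.integer(s), 2L)  # ideal 5/3 = 1.67
  expect_equal(attr(s, "realized_phase_rad"), 2 * pi * 2 / 5, tolerance = 1e-12)
  expect_error(pixel_shift_for_phase(1, 0), "period")
  expect_error(pixel_shift_for_phase(6.5, 0), "period")
})

test_that("generate_stripe_pattern reproduces the exact mirror logic", {
  p <- generate_stripe_pattern(6, 1, 6, 0, 0, 3)
  expect_identical(as.integer(p$pixels), c(1L, 1L, 1L, 0L, 0L, 0L))

  # 120 degrees = 2 px shift at period 6
  p2 <- generate_stripe_pattern(6, 1, 6, 0, 2 * pi / 3, 3)
  expect_identical(as.integer(p2$pixels), c(0L, 0L, 1L, 1L, 1L, 0L))

  # longer row: periodic continuation
  p12 <- generate_stripe_pattern(12, 2, 6, 0, 0, 3)
  expect_identical(p12$pixels[1L, ], rep(c(1L, 1L, 1L, 0L, 0L, 0L), 2L))
  expect_identical(p12$pixels[1L, ], p12$pixels[2L, ])  # constant along y
})

test_that("axis-aligned patterns hold the exact duty fraction", {
  for (duty in 1:5) {
    p <- generate_stripe_pattern(24, 24, 6, 0, 0, duty)
    expect_equal(mean(p$pixels), duty / 6)
  }
  p90 <- generate_stripe_pattern(24, 24, 6, 90, 0, 3)
  expect_equal(mean(p90$pixels), 0.5)
  expect_identical(p90$pixels[, 1L], p90$pixels[, 24L])  # constant along x
})

test_that("phase of the pattern's fundamental harmonic matches the request", {
  # Brute-force oracle: the first Fourier coefficient of one period row.
  fundamental_phase <- function(row, period) {
    x <- seq_along(row) - 1
    v <- sum(row * exp(-2i * pi * x / period))
    Arg(v)
  }
  base <- generate_stripe_pattern(24, 1, 6, 0, 0, 3)
  ph0 <- fundamental_phase(base$pixels[1L, ], 6)
  for (shift_px in 0:5) {
    phase <- 2 * pi * shift_px / 6
    p <- generate_stripe_pattern(24, 1, 6, 0, phase, 3)
    # shifting the pattern by s px delays its fundamental by 2*pi*s/P
    d <- wrap_pi(fundamental_phase(p$pixels[1L, ], 6) - ph0 + phase)
    expect_lt(abs(d), 1e-9)
    # and equals an explicit roll of the base pattern
    rolled <- base$pixels[1L, ((seq_len(24) - 1 - shift_px) %% 24) + 1]
    expect_identical(p$pixels[1L, ], rolled)
  }
})

test_that("pattern_set is orientation-major with 9 members", {
  ps <- pattern_set(30, 30)
  expect_length(ps, 9L)
  expect_equal(vapply(ps, `[[`, numeric(1L), "orientation_deg"),
               rep(c(0, 60, 120), each = 3L))
  expect_equal(vapply(ps, `[[`, numeric(1L), "phase_rad"),
               rep(c(0, 2 * pi / 3, 4 * pi / 3), times = 3L))
})

test_that("sample_period_nm is the exact product", {
  expect_identical(sample_period_nm(33, 45), 1485)
  expect_identical(sample_period_nm(6, 45), 270)
})

test_that("patterns round-trip through PNG files", {
  dir <- withr::local_tempdir()
  ps <- pattern_set(24, 18)
  paths <- write_patterns(ps, dir)
  expect_length(paths, 9L)
  expect_true(file.exists(file.path(dir, "patterns.json")))
  back <- read_pattern(paths[[5L]])
  expect_identical(back, ps[[5L]]$pixels)
})

test_that("generate_stripe_pattern validates its inputs", {
  expect_error(generate_stripe_pattern(0, 4, 6, 0, 0, 3), "positive")
  expect_error(generate_stripe_pattern(8, 8, 1, 0, 0, 1), "period")
  expect_error(generate_stripe_pattern(8, 8, 6, 0, 0, 6), "duty")
  expect_error(generate_stripe_pattern(8, 8, 6, 0, 0, 0), "duty")
})
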
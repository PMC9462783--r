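test_that("launch_geometry covers the data with minimal blocks", {
  g <- launch_geometry(1024, 1024, 32, 32)
  expect_identical(g$grid_dims, c(32L, 32L))
  expect_identical(g$total_threads, 1024L * 1024L)
  expect_identical(g$overhang, 0L)

  g2 <- launch_geometry(100, 70, 32, 16)
  expect_identical(g2$grid_dims, c(4L, 5L))          # ceiling(100/32), ceiling(70/16)
  expect_identical(g2$total_threads, 4L * 5L * 32L * 16L)
  expect_identical(g2$overhang, g2$total_threads - 100L * 70L)

  # one thread per element degenerate case
  g3 <- launch_geometry(7, 3, 1, 1)
  expect_identical(g3$grid_dims, c(7L, 3L))
  expect_identical(g3$overhang, 0L)

  expect_error(launch_geometry(0, 10), "positive")
  expect_output(print(g), "blocks")
})

test_that("every element-wise op agrees between serial and threads backends", {
  set.seed(11)
  n <- 67L  # deliberately not a multiple of the 32-row tile
  a <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  b <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  r <- matrix(abs(rnorm(n * n)) + 0.1, n, n)
  cases <- list(
    add = list(a, b), sub = list(a, b), mul = list(a, b),
    conj_mul = list(a, b), magnitude = list(a), abs2 = list(a),
    cexp = list(Re(a)),
    wiener_ratio = list(a, r, 0.05),
    wiener_num_term = list(r, a), wiener_den_term = list(r),
    ratio_reg = list(a, r, 0.1)
  )
  expect_setequal(names(cases), list_elementwise_ops())
  for (op in names(cases)) {
    s <- do.call(elementwise, c(list(op), cases[[op]], list(backend = "serial")))
    t <- do.call(elementwise, c(list(op), cases[[op]], list(backend = "threads")))
    expect_equal(t, s, tolerance = 1e-12, info = op)
    expect_identical(dim(s), c(n, n))
  }
})

test_that("elementwise validates op, backend and shapes", {
  a <- matrix(1, 4, 4)
  expect_error(elementwise("nope", a), "not registered")
  expect_error(elementwise("add", a, a, backend = "gpu"), "not registered")
  expect_error(elementwise("add", a, matrix(1, 3, 3)), "shapes")
})

test_that("custom backends can be registered and used", {
  calls <- 0L
  register_backend("counting", function(f, args) {
    calls <<- calls + 1L
    do.call(f, args)
  })
  expect_true("counting" %in% list_backends())
  a <- matrix(rnorm(16), 4, 4)
  expect_equal(elementwise("add", a, a, backend = "counting"), 2 * a)
  expect_identical(calls, 1L)
})

test_that("the threads backend is exact on non-square and tiny inputs", {
  set.seed(12)
  for (shp in list(c(1L, 5L), c(33L, 2L), c(64L, 128L))) {
    a <- matrix(rnorm(prod(shp)), shp[1L], shp[2L])
    expect_equal(elementwise("abs2", a, backend = "threads"),
                 elementwise("abs2", a, backend = "serial"))
  }
})
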
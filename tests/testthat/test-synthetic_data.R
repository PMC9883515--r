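test_that("stack specs reject aliasing and too-fine wavelengths", {
  expect_error(synthetic_stack_spec(wavelength = 3, pixel_size = 2),
               "exceed 2 pixels")
  expect_error(synthetic_stack_spec(wavelength = 10, speed = 400,
                                    interval = 15), "aliasing")
})

test_that("planar generator is deterministic and matches its analytic form", {
  spec <- synthetic_stack_spec(noise_sd = 0.01, seed = 42)
  a <- planar_wave_stack(spec)
  b <- planar_wave_stack(spec)
  expect_identical(a$stack$frames, b$stack$frames)

  # noise-free, zero speed, no bleaching: frames identical over time
  spec0 <- synthetic_stack_spec(kind = "static", noise_sd = 0, seed = 1)
  s0 <- static_stack(spec0)
  expect_equal(s0$stack$frames[, , 1], s0$stack$frames[, , 5])

  # noise-free planar wave equals its closed form
  spec1 <- synthetic_stack_spec(noise_sd = 0, wavelength = 40, speed = 300,
                                angle = 0, H = 16, W = 64, T = 6)
  s1 <- planar_wave_stack(spec1)
  x <- (seq_len(64) - 1) * spec1$pixel_size
  t3 <- 2 * spec1$interval
  expected <- spec1$baseline + spec1$amplitude *
    (1 + cos(2 * pi / 40 * x - 2 * pi * 0.3 / 40 * t3)) / 2
  expect_equal(s1$stack$frames[1, , 3], expected, tolerance = 1e-12)
  expect_equal(s1$truth$v, c(300, 0))
})

test_that("bleaching is mono-exponential and aggregates are static", {
  ag <- data.frame(x = 10, y = 12, intensity = 3, radius = 2)
  spec <- synthetic_stack_spec(kind = "static", noise_sd = 0,
                               bleach_rate = 0.1, aggregates = ag,
                               H = 24, W = 24, T = 5)
  s <- static_stack(spec)
  f1 <- s$stack$frames[, , 1]; f4 <- s$stack$frames[, , 4]
  expect_equal(f4, f1 * exp(-0.1 * 3), tolerance = 1e-12)
  expect_true(s$truth$aggregate_mask[12, 10])
  expect_equal(which(f1 == max(f1), arr.ind = TRUE)[1, ],
               c(row = 12, col = 10))
})

test_that("stacks round-trip through 16-bit TIFF", {
  spec <- synthetic_stack_spec(H = 16, W = 16, T = 3, seed = 9)
  s <- planar_wave_stack(spec)$stack
  path <- withr::local_tempfile(fileext = ".tif")
  mx <- max(s$frames)
  write_stack_tiff(s, path)
  back <- read_stack_tiff(path, s$pixel_size, s$interval)
  expect_lt(max(abs(back$frames - s$frames / mx)), 1 / 65535)
  # second round trip is lossless
  write_stack_tiff(back, path, scale = 1)
  back2 <- read_stack_tiff(path, s$pixel_size, s$interval)
  expect_identical(back2$frames, back$frames)
})

test_that("seeded wave states snap wavelengths and respect symmetry", {
  p <- test_params_ratio(0.6)
  g <- small_grid(L = 200, N = 64)
  st <- seeded_wave_state(p, g, wavelength = 48, direction = 1)
  expect_true(attr(st, "snapped"))
  expect_equal(attr(st, "wavelength"), 50)

  up <- seeded_wave_state(p, g, 50, -1)
  dn <- seeded_wave_state(p, g, 50, +1)
  # mirror images: x -> -x maps one onto the other (periodic roll)
  flip <- function(m) m[c(1, rev(seq_len(nrow(m))[-1])), ]
  expect_equal(flip(dn$fields), up$fields, tolerance = 1e-10)

  # amplitude -> 0 reduces to the homogeneous steady state
  s0 <- seeded_wave_state(p, g, 50, 1, amp = 0)
  ss <- homogeneous_steady_state(p, g)
  expect_equal(s0$fields, ss$fields, tolerance = 1e-12)
})
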
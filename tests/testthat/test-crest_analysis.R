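make_planar <- function(speed = 300, angle = 0, noise_sd = 0.01,
                        wavelength = 60, T = 48, seed = 5, ...) {
  planar_wave_stack(synthetic_stack_spec(
    kind = "planar", wavelength = wavelength, speed = speed, angle = angle,
    noise_sd = noise_sd, T = T, seed = seed, ...))
}

test_that("phase map recovers the analytic phase of a traveling wave", {
  gen <- make_planar(noise_sd = 0)
  pm <- phase_map(gen$stack)
  expect_true(all(pm$mask))
  # phase advances by omega * dt per frame at a fixed pixel
  om_true <- 2 * pi * 0.3 / 60
  expect_equal(pm$omega, om_true, tolerance = 0.05)
  mid <- round(dim(pm$phase)[3] / 2)
  d <- pm$phase[, , mid + 1] - pm$phase[, , mid]
  d <- mean(atan2(sin(d), cos(d)))
  expect_equal(d, -om_true * 15, tolerance = 0.05)
  # spatial phase fits the plane k*x up to a constant
  ph <- pm$phase[3, , mid]
  x <- (seq_along(ph) - 1) * gen$stack$pixel_size
  expected <- (2 * pi / 60) * x
  resid <- ph - expected
  resid <- atan2(sin(resid - mean(resid)), cos(resid - mean(resid)))
  expect_lt(stats::sd(resid), 0.1)
})

test_that("constant stacks are fully masked", {
  st <- image_stack(array(1, c(8, 8, 6)), 2, 15)
  pm <- phase_map(st)
  expect_false(any(pm$mask))
  expect_true(all(is.na(pm$phase)))
  expect_equal(nrow(detect_crests(pm$phase[, , 1])), 0)
})

test_that("crest lines of a planar wave are spaced one wavelength apart", {
  gen <- make_planar(noise_sd = 0, wavelength = 60, W = 128, H = 32)
  pm <- phase_map(gen$stack)
  cr <- detect_crests(pm$phase[, , 2])
  expect_gt(nrow(cr), 0)
  # project on the propagation axis; crest abscissae cluster at multiples
  # of the wavelength in pixels (30 px)
  xs <- sort(unique(round(cr$x)))
  gaps <- diff(xs[c(diff(xs) > 5, FALSE)])
  gaps <- gaps[gaps > 5]
  expect_true(all(abs(gaps - 30) / 30 < 0.02))
})

test_that("crest displacement estimator recovers speed, direction and time
           symmetry", {
  gen <- make_planar(speed = 300, angle = 0, noise_sd = 0.005)
  res <- analyze_crests(gen$stack)
  expect_gt(nrow(res$records), 50)
  expect_equal(mean(res$records$v_x), 300, tolerance = 0.05)
  expect_lt(abs(mean(res$records$v_y)), 15)

  # time-reversed stack gives negated velocities
  rev_stack <- gen$stack
  rev_stack$frames <- rev_stack$frames[, , rev(seq_len(dim(rev_stack$frames)[3]))]
  res_rev <- analyze_crests(rev_stack)
  expect_equal(mean(res_rev$records$v_x), -300, tolerance = 0.05)
})

test_that("velocity filter removes exactly the sub-10%-of-median records", {
  rec <- data.frame(x = 1:5, y = 1:5,
                    v_x = c(1, 100, 100, 100, 100), v_y = 0,
                    frame = 1L)
  class(rec) <- c("crest_velocity_record", class(rec))
  out <- filter_velocities(rec)
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "removed"), 1L)
  expect_true(all(out$v_x == 100))

  # all-equal magnitudes: nothing removed
  rec2 <- rec; rec2$v_x <- 50
  expect_equal(nrow(filter_velocities(rec2)), 5)

  expect_equal(nrow(filter_velocities(rec[0, ])), 0)
})

test_that("direction summary bins, fractions and peak speed behave", {
  rec <- data.frame(x = 1, y = 1, v_x = 300, v_y = 0, frame = 1L)
  class(rec) <- c("crest_velocity_record", class(rec))
  s <- direction_summary(rec)
  expect_equal(s$downstream_fraction, 1)
  expect_equal(s$upstream_fraction, 0)
  expect_true(s$low_confidence)
  expect_true(abs(s$peak_speed - 300) <= 5)  # within the 10 nm/s bin

  # uniformly distributed angles: each 15-degree bin near 1/24
  set.seed(2)
  n <- 6000
  ang <- stats::runif(n, -pi, pi)
  rec2 <- data.frame(x = 1, y = 1, v_x = 200 * cos(ang),
                     v_y = 200 * sin(ang), frame = 1L)
  class(rec2) <- c("crest_velocity_record", class(rec2))
  s2 <- direction_summary(rec2)
  expect_equal(sum(s2$angular$fraction), 1, tolerance = 1e-12)
  expect_true(all(abs(s2$angular$fraction - 1 / 24) < 4 * sqrt(1 / 24 / n)))
  expect_equal(s2$downstream_fraction, 4 / 24, tolerance = 0.05)
  expect_equal(s2$upstream_fraction, 4 / 24, tolerance = 0.05)
})

test_that("static aggregates are removed by the filter without biasing the
           wave velocity", {
  ag <- data.frame(x = c(20, 70), y = c(20, 60), intensity = c(2, 2),
                   radius = c(3, 3))
  gen <- make_planar(speed = 300, noise_sd = 0.01, aggregates = ag)
  clean <- make_planar(speed = 300, noise_sd = 0.01)
  res <- analyze_crests(gen$stack)
  res_clean <- analyze_crests(clean$stack)
  expect_equal(mean(res$records$v_x), mean(res_clean$records$v_x),
               tolerance = 0.05)
})

test_that("end-to-end recovery across speeds and orientations", {
  for (cs in list(c(150, 30), c(400, 135), c(600, 280))) {
    gen <- make_planar(speed = cs[1], angle = cs[2], noise_sd = 0.02,
                       wavelength = 80, seed = 11)
    rec <- analyze_crests(gen$stack)$records
    vx <- stats::median(rec$v_x); vy <- stats::median(rec$v_y)
    speed <- sqrt(vx^2 + vy^2)
    ang <- atan2(vy, vx) * 180 / pi
    dang <- ((ang - cs[2] + 180) %% 360) - 180
    expect_equal(speed, cs[1], tolerance = 0.05)
    expect_lt(abs(dang), 5)
  }
})

test_that("rotating the stack by 90 degrees rotates the summary", {
  gen <- make_planar(speed = 300, angle = 0, noise_sd = 0.01, H = 96, W = 96)
  rot <- gen$stack
  rot$frames <- aperm(rot$frames, c(2, 1, 3))[dim(rot$frames)[2]:1, , ]
  res0 <- analyze_crests(gen$stack)$summary
  res90 <- analyze_crests(rot)$summary
  rec90 <- analyze_crests(rot)$records
  ang90 <- atan2(mean(rec90$v_y), mean(rec90$v_x)) * 180 / pi
  expect_equal(abs(ang90), 90, tolerance = 5 / 90)
  rec0 <- analyze_crests(gen$stack)$records
  expect_equal(stats::median(sqrt(rec90$v_x^2 + rec90$v_y^2)),
               stats::median(sqrt(rec0$v_x^2 + rec0$v_y^2)),
               tolerance = 0.05)
})

test_that("spiral stacks have no preferred direction", {
  spec <- synthetic_stack_spec(kind = "spiral", wavelength = 40, speed = 300,
                               noise_sd = 0.01, H = 160, W = 160, T = 32,
                               seed = 3)
  gen <- spiral_stack(spec)
  res <- analyze_crests(gen$stack)
  s <- res$summary
  expect_gt(s$n, 100)
  # no 15-degree segment dominates strongly
  expect_lt(max(s$angular$fraction), 0.2)
  expect_lt(abs(s$downstream_fraction - s$upstream_fraction), 0.15)
})
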
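test_that("a uniform steady state is a fixed point, also under flow", {
  for (v in c(0, 3)) {
    p <- test_params_ratio(0.6, v_f = v)
    g <- small_grid(N = 64)
    ss <- homogeneous_steady_state(p, g)
    tr <- simulate_min(ss, p, g, min_schedule(0.05, 100, 200))
    last <- tr$states[[length(tr$states)]]
    rel <- max(abs(last$fields - ss$fields)) / max(ss$fields)
    expect_lt(rel, 1e-8)
  }
})

test_that("pure advection translates a bulk profile without decay", {
  p <- min_params(k_D = 0, k_dD = 0, k_dEr = 0, k_dEi = 0, k_de = 0,
                  lambda = 0, mu = 0, D_m = 0, D_c = 0, v_f = 2,
                  n_D_mean = 1, n_E_mean = 0)
  g <- small_grid(L = 100, N = 128)
  gauss <- 1 + exp(-(g$x - 30)^2 / (2 * 5^2))
  f <- matrix(0, g$N, 6); f[, 3] <- gauss; f[, 1] <- 1
  tr <- simulate_min(field_state(f), p, g, min_schedule(0.05, 10, 20))
  last <- tr$states[[length(tr$states)]]$fields
  # exact periodic translation of the Gaussian by v*t
  ref <- 1 + sapply(g$x, function(x) {
    d <- (x - 30 - 20) %% g$L
    d <- min(d, g$L - d)
    exp(-d^2 / (2 * 5^2))
  })
  expect_equal(unname(last[, 3]), ref, tolerance = 1e-7)
  # membrane species are never advected
  expect_equal(unname(last[, 1]), rep(1, g$N), tolerance = 1e-12)
})

test_that("pure diffusion decays a Fourier mode at exp(-D q^2 t)", {
  p <- min_params(k_D = 0, k_dD = 0, k_dEr = 0, k_dEi = 0, k_de = 0,
                  lambda = 0, mu = 0, D_m = 0.3, D_c = 10, v_f = 0,
                  n_D_mean = 1, n_E_mean = 0)
  g <- small_grid(L = 100, N = 64)
  q <- 2 * pi * 3 / g$L
  f <- matrix(0, g$N, 6)
  f[, 1] <- 1 + 0.5 * cos(q * g$x)   # membrane, D_m
  f[, 4] <- 1 + 0.5 * cos(q * g$x)   # bulk, D_c
  tr <- simulate_min(field_state(f), p, g, min_schedule(0.05, 20, 100))
  last <- tr$states[[length(tr$states)]]$fields
  amp <- function(v) max(v) - 1
  expect_equal(amp(last[, 1]), 0.5 * exp(-0.3 * q^2 * 20), tolerance = 0.01)
  expect_equal(amp(last[, 4]), 0.5 * exp(-10 * q^2 * 20), tolerance = 0.01)
})

test_that("total densities are conserved to near machine precision", {
  p <- test_params_ratio(0.6, v_f = 2)
  g <- small_grid(N = 96)
  init <- noisy_homogeneous_state(p, g, seed = 4)
  tr <- simulate_min(init, p, g, min_schedule(0.02, 20, 250))  # 1000 steps
  expect_lt(tr$max_rel_drift, 1e-6)
  expect_true(tr$valid)
})

test_that("simulation is deterministic and mirror-equivariant at v_f = 0", {
  p <- test_params_ratio(0.6)
  g <- small_grid(N = 64)
  init <- noisy_homogeneous_state(p, g, seed = 8)
  sc <- min_schedule(0.02, 30, 300)
  t1 <- simulate_min(init, p, g, sc)
  t2 <- simulate_min(init, p, g, sc)
  expect_identical(t1$states[[length(t1$states)]]$fields,
                   t2$states[[length(t2$states)]]$fields)

  flip <- function(m) m[c(1, rev(seq_len(nrow(m))[-1])), , drop = FALSE]
  mirr <- field_state(flip(init$fields))
  t3 <- simulate_min(mirr, p, g, sc)
  expect_equal(flip(t3$states[[length(t3$states)]]$fields),
               t1$states[[length(t1$states)]]$fields, tolerance = 1e-10)
})

test_that("flipping v_f and x together maps trajectories onto each other", {
  g <- small_grid(N = 64)
  p_plus <- test_params_ratio(0.6, v_f = 2)
  p_minus <- test_params_ratio(0.6, v_f = -2)
  init <- noisy_homogeneous_state(p_plus, g, seed = 12)
  flip <- function(m) m[c(1, rev(seq_len(nrow(m))[-1])), , drop = FALSE]
  sc <- min_schedule(0.02, 30, 300)
  a <- simulate_min(init, p_plus, g, sc)
  b <- simulate_min(field_state(flip(init$fields)), p_minus, g, sc)
  expect_equal(flip(b$states[[length(b$states)]]$fields),
               a$states[[length(a$states)]]$fields, tolerance = 1e-10)
})

test_that("skeleton variant equals the full model at mu = 0 with no latent
           MinE", {
  g <- small_grid(N = 64)
  p_full <- test_params_ratio(0.3, v_f = 1, mu = 0)
  p_skel <- as_skeleton(test_params_ratio(0.3, v_f = 1))
  ss <- homogeneous_steady_state(p_skel, g)
  init <- field_state(ss$fields * (1 + 0.01 * cos(2 * pi * 2 * g$x / g$L)))
  init$fields[, "c_Ei"] <- 0
  sc <- min_schedule(0.02, 50, 500)
  a <- simulate_min(init, p_full, g, sc)
  b <- simulate_min(init, p_skel, g, sc)
  expect_equal(a$states[[length(a$states)]]$fields,
               b$states[[length(b$states)]]$fields, tolerance = 1e-12)
})

test_that("kymographs encode translation and stationarity", {
  g <- small_grid(L = 100, N = 64)
  p <- test_params()
  # hand-built translating profile trajectory
  times <- seq(0, 90, by = 10)
  c_true <- 0.5
  states <- lapply(times, function(t) {
    f <- matrix(1, g$N, 6)
    f[, 1] <- 2 + cos(2 * pi * (g$x - c_true * t) / g$L)
    field_state(f, t = t)
  })
  traj <- structure(list(states = states, times = times, params = p,
                         grid = g,
                         schedule = min_schedule(1, 90, 1)),
                    class = "min_trajectory")
  k <- kymograph(traj, "m_d")
  expect_equal(dim(k), c(g$N, length(times)))
  # crest position advances by c * dt per frame
  crest <- apply(k, 2, which.max)
  dx <- diff(g$x[crest])
  expect_equal(mean(dx %% g$L), c_true * 10, tolerance = 0.2)

  pv <- pattern_velocity(traj, window = 1)
  expect_equal(pv$velocity, c_true, tolerance = 0.02)

  # uniform state: constant image
  states_u <- lapply(times, function(t) field_state(matrix(1, g$N, 6), t))
  traj_u <- traj; traj_u$states <- states_u
  expect_equal(max(kymograph(traj_u)) - min(kymograph(traj_u)), 0)
  expect_error(kymograph(structure(list(states = list()),
                                   class = "min_trajectory")), "empty")
})

test_that("grid refinement leaves wavelength and speed nearly unchanged", {
  p <- test_params_ratio(0.6, v_f = 2)
  res <- lapply(c(256, 512), function(N) {
    g <- min_grid(200, N)
    init <- seeded_wave_state(p, g, 50, +1)
    tr <- simulate_min(init, p, g, min_schedule(0.02, 300, 500))
    tm <- minflow:::.continue(tr, p, 300, min_schedule(0.02, 300, 500))
    pattern_velocity(tm, window = 1)
  })
  expect_equal(res[[1]]$wavelength, res[[2]]$wavelength, tolerance = 0.02)
  expect_equal(res[[1]]$velocity, res[[2]]$velocity, tolerance = 0.05)
})
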
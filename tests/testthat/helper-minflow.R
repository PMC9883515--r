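# shared fixtures: a fast, well-behaved parameter point and small grids
test_params <- function(...) min_param_set("invitro_switch_v1", ...)

test_params_ratio <- function(ratio, v_f = 0, ...)
  min_params_at_ratio(ratio, v_f = v_f, ...)

small_grid <- function(L = 200, N = 128) min_grid(L, N)

random_state <- function(params, grid, seed = 1) {
  withr::with_seed(seed, {
    f <- matrix(stats::runif(grid$N * 6, 0, 100), grid$N, 6)
    colnames(f) <- c("m_d", "m_de", "c_DD", "c_DT", "c_Er", "c_Ei")
    if (params$variant == "skeleton") f[, "c_Ei"] <- 0
    field_state(f)
  })
}

# measure complex growth of lateral Fourier mode k by seeding the leading
# eigenvector of the linearized (advected) operator at that wavenumber with
# a tiny amplitude: returns measured growth rate and phase velocity
measure_mode_growth <- function(params, grid, k_mode, t_end = 30,
                                dt = 0.02, amp = 1e-6, window = c(0.4, 1)) {
  q <- 2 * pi * k_mode / grid$L
  ss <- homogeneous_steady_state(params, grid)
  eg <- eigen(jacobian_at_q(params, homogeneous_steady_state(params), q))
  v <- eg$vectors[, which.max(Re(eg$values))]
  u0 <- ss$fields[1, ]
  vs <- v / max(abs(v) / pmax(u0, 1e-12 * max(u0)))
  pert <- amp * Re(outer(exp(1i * q * grid$x), vs))
  init <- field_state(ss$fields + pert)
  tr <- simulate_min(init, params, grid,
                     min_schedule(dt, t_end, save_every = 25L))
  m <- species_matrix(tr, "m_d")
  co <- t(apply(m - rowMeans(m), 1, stats::fft))[, k_mode + 1]
  tt <- tr$times
  i <- seq.int(max(1, ceiling(length(tt) * window[1])),
               floor(length(tt) * window[2]))
  gfit <- stats::lm(log(Mod(co[i])) ~ tt[i])
  pfit <- stats::lm(minflow:::.unwrap(Arg(co[i])) ~ tt[i])
  list(growth = unname(stats::coef(gfit)[2]),
       phase_velocity = -unname(stats::coef(pfit)[2]) / q)
}
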
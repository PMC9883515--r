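#' Integration schedule
#'
#' @param dt time step (s).  The reaction sub-step is explicit (RK4), so
#'   `dt` must resolve the fastest kinetic rate; linear transport is exact
#'   in Fourier space and imposes no CFL restriction.
#' @param t_end end time (s).
#' @param save_every save a snapshot every this many steps.
#' @param seed RNG seed recorded with the run and used for initial noise.
#' @export
min_schedule <- function(dt, t_end, save_every = 100L, seed = 1L) {
  stopifnot(dt > 0, t_end >= dt)
  structure(list(dt = dt, t_end = t_end,
                 save_every = as.integer(save_every),
                 seed = as.integer(seed)),
            class = "min_schedule")
}

#' Advance a field state by one time step
#'
#' One Strang-split step: half-step of exact spectral transport (membrane
#' diffusion for `m_d`, `m_de`; bulk diffusion plus advection at `v_f` for
#' the bulk fields — membrane species are never advected), a full RK4
#' reaction step, and a second transport half-step.  Bulk MinE is advected
#' only if `params$advect_minE` is `TRUE`.
#'
#' @param state a `field_state` on `grid`.
#' @param params a `min_params`.
#' @param grid a `min_grid`.
#' @param dt time step (s).
#' @return the advanced `field_state`.
#' @export
min_step <- function(state, params, grid, dt) {
  traj <- simulate_min(state, params, grid,
                       min_schedule(dt, dt, save_every = 1L))
  traj$states[[2]]
}

#' Simulate the Min reaction--diffusion--advection dynamics
#'
#' Integrates the six-species dynamics on a 1D laterally periodic domain
#' with the bulk dimension integrated out.  Deterministic given
#' `(initial, params, schedule)`.  Total MinD and MinE densities are
#' monitored; drift beyond `1e-4` relative flags the run as invalid.
#'
#' @param initial a `field_state` (see [noisy_homogeneous_state()] and
#'   [seeded_wave_state()] for standard initial conditions).
#' @param params a `min_params`.
#' @param grid a `min_grid`.
#' @param schedule a `min_schedule`.
#' @return a `min_trajectory`: list of `field_state` snapshots, times,
#'   parameter/grid/schedule metadata and a conservation log.
#' @export
simulate_min <- function(initial, params, grid, schedule) {
  stopifnot(inherits(initial, "field_state"), inherits(params, "min_params"),
            inherits(grid, "min_grid"), inherits(schedule, "min_schedule"))
  if (nrow(initial$fields) != grid$N) stop("initial state does not match grid")
  f0 <- initial$fields
  if (params$variant == "skeleton" &&
      max(abs(f0[, "c_Ei"])) > 1e-9 * params$n_D_mean)
    stop("skeleton variant requires c_Ei identically zero")
  n_steps <- max(1L, as.integer(round(schedule$t_end / schedule$dt)))
  scale <- params$n_D_mean + params$n_E_mean
  res <- sim_core(f0, grid$L,
                  c(params$k_D, params$k_dD, params$k_dEr, params$k_dEi,
                    params$k_de, params$lambda, params$mu),
                  params$D_m, params$D_c, params$v_f,
                  params$advect_minE,
                  params$variant == "reduced_switch", params$n_E_mean,
                  schedule$dt, n_steps, schedule$save_every,
                  neg_abort = 1e-2 * scale)
  states <- lapply(seq_len(dim(res$states)[3]), function(i) {
    m <- res$states[, , i]
    colnames(m) <- .min_fields
    field_state(m, t = initial$t + res$times[i])
  })
  cons <- t(vapply(states, total_densities, numeric(2)))
  drift <- apply(cons, 2, function(v) max(abs(v - v[1])) / max(v[1], 1e-12))
  traj <- structure(list(states = states,
                         times = initial$t + res$times,
                         params = params, grid = grid, schedule = schedule,
                         conservation = cons,
                         max_rel_drift = max(drift),
                         valid = max(drift) < 1e-4),
                    class = "min_trajectory")
  if (!traj$valid)
    warning("conservation drift ", signif(max(drift), 3),
            " exceeds 1e-4; run flagged invalid")
  traj
}

#' @export
print.min_trajectory <- function(x, ...) {
  cat("Min trajectory:", length(x$states), "snapshots, t in [",
      signif(x$times[1], 4), ",", signif(max(x$times), 4), "] s,",
      x$grid$N, "grid points on L =", x$grid$L, "um\n")
  cat("  variant:", x$params$variant, " v_f =", x$params$v_f,
      "um/s  max relative conservation drift:",
      signif(x$max_rel_drift, 3), "\n")
  invisible(x)
}

#' Extract a species field over time
#'
#' @param traj a `min_trajectory`.
#' @param species field name (default membrane MinD `"m_d"`).
#' @return matrix, one row per snapshot, one column per grid point.
#' @export
species_matrix <- function(traj, species = "m_d") {
  stopifnot(species %in% .min_fields)
  t(vapply(traj$states, function(s) s$fields[, species],
           numeric(traj$grid$N)))
}

#' Kymograph of a species
#'
#' Space-time map of one species along the lateral axis; stripe slope
#' encodes the wave velocity.
#'
#' @param traj a `min_trajectory`.
#' @param species field name.
#' @return matrix (space x time) with attributes `x` and `t`, suitable for
#'   `image()` or [write_stack_tiff()].
#' @export
kymograph <- function(traj, species = "m_d") {
  if (!length(traj$states)) stop("empty trajectory")
  k <- t(species_matrix(traj, species))
  attr(k, "x") <- traj$grid$x
  attr(k, "t") <- traj$times
  k
}

#' Noisy homogeneous initial condition
#'
#' The homogeneous steady state with a small multiplicative uniform
#' perturbation (amplitude `amp`), the standard protocol for letting the
#' intrinsic instability select a pattern.
#'
#' @param params a `min_params`.
#' @param grid a `min_grid`.
#' @param amp relative noise amplitude.
#' @param seed RNG seed (recorded; the generator state is restored).
#' @export
noisy_homogeneous_state <- function(params, grid, amp = 1e-3, seed = 1L) {
  ss <- homogeneous_steady_state(params, grid)
  f <- ss$fields
  noise <- withr::with_seed(seed,
    matrix(stats::runif(length(f), -amp, amp), nrow = nrow(f)))
  st <- field_state(f * (1 + noise), t = 0)
  attr(st, "seed") <- seed
  st
}
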
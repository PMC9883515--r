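#' Signed pattern velocity from the dominant Fourier mode
#'
#' Measures the drift velocity of the developed pattern as the phase drift
#' rate of the dominant spatial Fourier mode of membrane MinD over the
#' measurement window, divided by the mode wavenumber.  Positive velocities
#' point along +x (the flow direction when `v_f > 0`).
#'
#' @param traj a `min_trajectory`.
#' @param window fraction of the trajectory (from the end) used for the
#'   measurement.
#' @param min_contrast pattern-presence threshold: spatial sd of `m_d`
#'   must exceed this fraction of its mean.
#' @return list with `velocity` (um/s, `NA` if no pattern), `se` (regression
#'   standard error), `wavelength` (um), `amplitude` (spatial sd / mean) and
#'   `classification` in `upstream/downstream/stationary/no_pattern`
#'   (`upstream`/`downstream` only defined for `v_f != 0`; at `v_f = 0`
#'   nonzero drift is labeled by its sign as `"+x"`/`"-x"`).
#' @export
pattern_velocity <- function(traj, window = 0.5, min_contrast = 0.01) {
  m <- species_matrix(traj, "m_d")
  tt <- traj$times
  i0 <- max(1L, ceiling(nrow(m) * (1 - window)))
  m <- m[i0:nrow(m), , drop = FALSE]; tt <- tt[i0:length(tt)]
  contrast <- mean(apply(m, 1, stats::sd) / rowMeans(m))
  if (!is.finite(contrast) || contrast < min_contrast)
    return(list(velocity = NA_real_, se = NA_real_, wavelength = NA_real_,
                amplitude = contrast, classification = "no_pattern"))
  N <- ncol(m); L <- traj$grid$L
  co <- t(apply(m - rowMeans(m), 1, stats::fft))[, 2:floor(N / 2),
                                                 drop = FALSE]
  k_dom <- which.max(colMeans(abs(co)))
  q <- 2 * pi * k_dom / L
  ph <- .unwrap(Arg(co[, k_dom]))
  fit <- stats::lm(ph ~ tt)
  vel <- -unname(stats::coef(fit)[2]) / q
  r <- stats::residuals(fit)
  sxx <- sum((tt - mean(tt))^2)
  se <- if (length(tt) > 2 && sxx > 0)
    sqrt(sum(r^2) / (length(tt) - 2) / sxx) / q else NA_real_
  # resolution bound on a zero-velocity call
  vmin <- (L / N) / (max(tt) - min(tt))
  cls <- if (abs(vel) < vmin) "stationary"
         else if (traj$params$v_f == 0) if (vel > 0) "+x" else "-x"
         else if (sign(vel) == sign(traj$params$v_f)) "downstream"
         else "upstream"
  list(velocity = vel, se = se, wavelength = L / k_dom,
       amplitude = contrast, classification = cls)
}

.unwrap <- function(p) {
  d <- diff(p)
  cumsum(c(p[1], d - 2 * pi * round(d / (2 * pi))))
}

#' Dominant pattern wavelength
#'
#' `2*pi/q` of the spectral peak of mean-removed membrane MinD, with
#' parabolic interpolation of the log-amplitude peak.
#'
#' @param x a `field_state` or `min_trajectory` (last snapshot used).
#' @param grid the `min_grid` (taken from the trajectory if omitted).
#' @param min_contrast flat-spectrum threshold, as in [pattern_velocity()].
#' @return wavelength (um), or `NA` if no pattern.
#' @export
dominant_wavelength <- function(x, grid = NULL, min_contrast = 0.01) {
  if (inherits(x, "min_trajectory")) {
    grid <- x$grid
    x <- x$states[[length(x$states)]]
  }
  stopifnot(inherits(x, "field_state"), inherits(grid, "min_grid"))
  v <- x$fields[, "m_d"]
  if (stats::sd(v) / mean(v) < min_contrast) return(NA_real_)
  a <- abs(stats::fft(v - mean(v)))[2:floor(length(v) / 2)]
  k <- which.max(a)
  kk <- k
  if (k > 1 && k < length(a)) {
    y <- log(a[(k - 1):(k + 1)] + .Machine$double.eps)
    d <- (y[1] - y[3]) / (2 * (y[1] - 2 * y[2] + y[3]))
    if (is.finite(d) && abs(d) < 1) kk <- k + d
  }
  grid$L / kk
}

#' Continue a simulation from the last state of a trajectory
#' @keywords internal
.continue <- function(traj, params, t_extra, schedule) {
  sc <- min_schedule(schedule$dt, t_extra, schedule$save_every,
                     schedule$seed)
  simulate_min(traj$states[[length(traj$states)]], params, traj$grid, sc)
}

#' Adiabatic parameter sweep
#'
#' Walks an ordered path of values of one control parameter (`v_f` or the
#' E:D ratio), continuing each simulation from the final state of the
#' previous one: relax for `t_relax`, then measure for `t_measure`.  This is
#' the protocol behind the hysteresis loops and the phase-diagram boundary
#' read off from a developed pattern.
#'
#' @param params base `min_params` (its `v_f` / `n_E_mean` is overridden
#'   along the path).
#' @param grid a `min_grid`.
#' @param control `"v_f"` or `"ratio"` (E:D, scaling `n_E_mean` at fixed
#'   `n_D_mean`).
#' @param path ordered control values.
#' @param init initial `field_state`; defaults to the noisy homogeneous
#'   state at the first path value.
#' @param t_relax,t_measure relaxation and measurement windows (s); defaults
#'   should cover >= 10 pattern periods and the measured period is part of
#'   the returned table so adequacy is auditable.
#' @param dt,save_every integration controls.
#' @param seed seed for the initial noise.
#' @return data frame with one row per path value: control value, signed
#'   velocity, wavelength, amplitude, classification, period; the final
#'   state is attached as `attr(, "final_state")`.
#' @export
adiabatic_sweep <- function(params, grid, control = c("v_f", "ratio"), path,
                            init = NULL, t_relax = 400, t_measure = 400,
                            dt = 0.02, save_every = 250L, seed = 1L) {
  control <- match.arg(control)
  at <- function(v) {
    p <- params
    if (control == "v_f") p$v_f <- v else p$n_E_mean <- v * p$n_D_mean
    p
  }
  p1 <- at(path[1])
  state <- if (is.null(init)) noisy_homogeneous_state(p1, grid, seed = seed)
           else init
  rows <- vector("list", length(path))
  for (i in seq_along(path)) {
    p <- at(path[i])
    if (control == "ratio") state <- .match_totals(state, p)
    sc <- min_schedule(dt, t_relax, save_every, seed)
    tm <- tryCatch({
      tr <- simulate_min(state, p, grid, sc)
      .continue(tr, p, t_measure, sc)
    }, error = function(e) e)
    if (inherits(tm, "error")) {
      # stage failure is recorded and the sweep continues from a fresh
      # noisy homogeneous state at the current control value
      rows[[i]] <- data.frame(control = path[i], velocity = NA_real_,
                              wavelength = NA_real_, amplitude = NA_real_,
                              classification = "failed", period = NA_real_)
      state <- noisy_homogeneous_state(p, grid, seed = seed)
      next
    }
    pv <- pattern_velocity(tm, window = 1)
    period <- if (is.finite(pv$velocity) && abs(pv$velocity) > 0)
      pv$wavelength / abs(pv$velocity) else NA_real_
    rows[[i]] <- data.frame(control = path[i], velocity = pv$velocity,
                            wavelength = pv$wavelength,
                            amplitude = pv$amplitude,
                            classification = pv$classification,
                            period = period)
    state <- tm$states[[length(tm$states)]]
    state$t <- 0
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- control
  attr(out, "final_state") <- state
  out
}

# Adjust a carried state to the totals demanded by new parameters: an E:D
# sweep step adds/removes bulk MinE (scaling the reactive and latent pools
# uniformly), emulating a change of the solution composition.
.match_totals <- function(state, params) {
  f <- state$fields
  td <- total_densities(state)
  dE <- params$n_E_mean - td[["n_E"]]
  if (dE > 1e-12 * max(1, params$n_E_mean)) {
    pool <- mean(f[, "c_Er"] + f[, "c_Ei"])
    if (pool > 1e-12) {
      s <- (pool + dE) / pool
      f[, "c_Er"] <- f[, "c_Er"] * s
      f[, "c_Ei"] <- f[, "c_Ei"] * s
    } else {
      f[, "c_Er"] <- f[, "c_Er"] + dE
    }
  } else if (dE < -1e-12 * max(1, params$n_E_mean)) {
    # drain the bulk pools first; any remaining excess is stripped from
    # the membrane complex, leaving its MinD behind as m_d
    pool <- mean(f[, "c_Er"] + f[, "c_Ei"])
    take <- min(pool, -dE)
    if (pool > 1e-12) {
      s <- (pool - take) / pool
      f[, "c_Er"] <- f[, "c_Er"] * s
      f[, "c_Ei"] <- f[, "c_Ei"] * s
    }
    rem <- -dE - take
    if (rem > 1e-12) {
      mde <- mean(f[, "m_de"])
      s2 <- max(0, (mde - rem) / mde)
      f[, "m_d"] <- f[, "m_d"] + (1 - s2) * f[, "m_de"]
      f[, "m_de"] <- f[, "m_de"] * s2
    }
  }
  field_state(pmax(f, 0), t = state$t)
}

#' Direction classification at one parameter point
#'
#' Runs the three-seed multistability protocol: a noisy homogeneous initial
#' state plus, optionally, downstream- and upstream-seeded traveling waves.
#' A point is multistable when different initial conditions retain opposite
#' nonzero directions.
#'
#' @param params `min_params` at the point (with `v_f` set).
#' @param grid a `min_grid`.
#' @param seeds subset of `c("homogeneous", "down", "up")`.
#' @param seed_wavelength wavelength of the seeded waves (um).
#' @param t_relax,t_measure,dt,save_every,seed as in [adiabatic_sweep()].
#' @return data frame, one row per initial condition, plus
#'   `attr(, "multistable")`.
#' @export
classify_point <- function(params, grid,
                           seeds = c("homogeneous", "down", "up"),
                           seed_wavelength = NULL,
                           t_relax = 600, t_measure = 400, dt = 0.02,
                           save_every = 250L, seed = 1L) {
  if (is.null(seed_wavelength)) seed_wavelength <- grid$L / 4
  rows <- lapply(seeds, function(sd) {
    init <- switch(sd,
      homogeneous = noisy_homogeneous_state(params, grid, seed = seed),
      down = seeded_wave_state(params, grid, seed_wavelength, +1),
      up = seeded_wave_state(params, grid, seed_wavelength, -1))
    tr <- simulate_min(init, params, grid,
                       min_schedule(dt, t_relax, save_every, seed))
    tm <- .continue(tr, params, t_measure,
                    min_schedule(dt, t_measure, save_every, seed))
    pv <- pattern_velocity(tm, window = 1)
    data.frame(init = sd, velocity = pv$velocity,
               wavelength = pv$wavelength,
               classification = pv$classification)
  })
  out <- do.call(rbind, rows)
  dirs <- out$classification[out$classification %in%
                               c("upstream", "downstream")]
  attr(out, "multistable") <- length(unique(dirs)) > 1
  out
}

#' Phase diagram over E:D ratio and flow velocity
#'
#' Classifies the propagation direction on a grid of (E:D, v_f) points with
#' the three-seed protocol, labeling each point exclusively-downstream,
#' exclusively-upstream, multistable, or no-pattern.  Unclassifiable points
#' are flagged, never dropped.
#'
#' @param params base `min_params`.
#' @param grid a `min_grid`.
#' @param ratios E:D values.
#' @param v_fs flow velocities (um/s).
#' @param ... passed to [classify_point()].
#' @return data frame with one row per grid point.
#' @export
phase_diagram <- function(params, grid, ratios, v_fs, ...) {
  rows <- list()
  for (r in ratios) for (v in v_fs) {
    p <- params; p$n_E_mean <- r * p$n_D_mean; p$v_f <- v
    cl <- tryCatch(classify_point(p, grid, ...), error = function(e) NULL)
    lab <- if (is.null(cl)) "unclassifiable" else {
      dirs <- unique(cl$classification[cl$classification %in%
                                         c("upstream", "downstream")])
      if (attr(cl, "multistable")) "multistable"
      else if (identical(dirs, "upstream")) "upstream"
      else if (identical(dirs, "downstream")) "downstream"
      else if (all(cl$classification == "no_pattern")) "no_pattern"
      else "unclassifiable"
    }
    rows[[length(rows) + 1]] <- data.frame(ratio = r, v_f = v, label = lab)
  }
  do.call(rbind, rows)
}

#' Reversal flow velocity as a function of pattern wavelength
#'
#' For each requested wavelength, seeds a downstream traveling wave and
#' ramps the flow velocity upward until the propagation direction reverses;
#' reports the reversal velocity per wavelength and whether it is
#' non-decreasing in wavelength (longer waves should reverse later).
#'
#' @param params `min_params` at fixed E:D.
#' @param grid a `min_grid`.
#' @param wavelengths >= 3 distinct seeded wavelengths (um); duplicates are
#'   grouped.
#' @param v_path increasing flow velocities to walk through.
#' @param ... passed to [adiabatic_sweep()].
#' @return list with per-wavelength `reversal_v` (NA = open-ended, no
#'   reversal in range) and `monotone` flag.
#' @export
wavelength_reversal_correlation <- function(params, grid, wavelengths,
                                            v_path, ...) {
  wavelengths <- sort(unique(wavelengths))
  if (length(wavelengths) < 3)
    stop("need at least 3 distinct wavelengths")
  rev_v <- vapply(wavelengths, function(w) {
    p <- params; p$v_f <- v_path[1]
    init <- seeded_wave_state(p, grid, w, +1)
    sw <- adiabatic_sweep(p, grid, "v_f", v_path, init = init, ...)
    i <- which(sw$classification == "upstream")[1]
    if (is.na(i)) NA_real_ else sw$v_f[i]
  }, numeric(1))
  known <- !is.na(rev_v)
  list(wavelength = wavelengths, reversal_v = rev_v,
       monotone = all(diff(rev_v[known]) >= 0),
       open_ended = any(!known))
}

#' MinE-advection ablation
#'
#' Classifies the propagation direction in two matched runs that differ
#' only in whether bulk MinE is advected, the numerical experiment that
#' shows MinE advection is not what sets the direction.
#'
#' @param params `min_params` with `advect_minE = TRUE`.
#' @param grid a `min_grid`.
#' @param seeds initial-condition protocol passed to [classify_point()];
#'   a seeded wave is useful where spontaneous development is slow.
#' @param ... passed to [classify_point()].
#' @return data frame with rows `advected` / `not_advected`.
#' @export
minE_advection_ablation <- function(params, grid, seeds = "homogeneous",
                                    ...) {
  run1 <- classify_point(params, grid, seeds = seeds, ...)
  p2 <- params; p2$advect_minE <- FALSE
  run2 <- classify_point(p2, grid, seeds = seeds, ...)
  data.frame(minE = c("advected", "not_advected"),
             classification = c(run1$classification, run2$classification),
             velocity = c(run1$velocity, run2$velocity))
}
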
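#' Kinetic parameters for a Min model variant
#'
#' Bundles all rate constants, diffusivities, the bulk flow velocity and the
#' total (conserved) protein densities for one model variant.  The bulk is
#' treated as vertically integrated: bulk concentrations are areal densities
#' (1/um^2) and the bulk-height factor of the attachment rate constants is
#' absorbed into `k_D`, `k_dD`, `k_dEr` and `k_dEi`, which therefore carry
#' units of 1/s (`k_D`) and um^2/s (the recruitment rates).
#'
#' @param k_D basal MinD attachment rate (1/s, height-absorbed).
#' @param k_dD MinD self-recruitment rate (um^2/s).
#' @param k_dEr recruitment rate of reactive bulk MinE (um^2/s).
#' @param k_dEi recruitment rate of latent bulk MinE (um^2/s).
#' @param k_de MinDE complex detachment rate (1/s).
#' @param lambda nucleotide exchange rate MinD-ADP -> MinD-ATP (1/s).
#' @param mu MinE conformational switching rate, reactive -> latent (1/s).
#' @param D_m membrane diffusivity (um^2/s).
#' @param D_c bulk diffusivity (um^2/s).
#' @param v_f signed bulk flow velocity; +x is downstream (um/s).
#' @param n_D_mean,n_E_mean mean total MinD / MinE densities (1/um^2).
#' @param variant one of `"full"`, `"skeleton"`, `"reduced_switch"`.
#'   The skeleton variant has no MinE switch: `mu` is forced to 0 and the
#'   latent pool `c_Ei` stays identically zero.
#' @param advect_minE logical; if `FALSE` the bulk MinE fields are exempt
#'   from advection (ablation switch used to test the role of MinE
#'   transport).
#' @return An object of class `min_params`.
#' @export
min_params <- function(k_D, k_dD, k_dEr, k_dEi, k_de, lambda, mu,
                       D_m, D_c, v_f = 0,
                       n_D_mean, n_E_mean,
                       variant = c("full", "skeleton", "reduced_switch"),
                       advect_minE = TRUE) {
  variant <- match.arg(variant)
  rates <- c(k_D = k_D, k_dD = k_dD, k_dEr = k_dEr, k_dEi = k_dEi,
             k_de = k_de, lambda = lambda, mu = mu, D_m = D_m, D_c = D_c)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and diffusivities must be finite and >= 0")
  if (!is.finite(n_D_mean) || n_D_mean <= 0) stop("n_D_mean must be > 0")
  if (!is.finite(n_E_mean) || n_E_mean < 0) stop("n_E_mean must be >= 0")
  if (variant == "skeleton") mu <- 0
  structure(list(k_D = k_D, k_dD = k_dD, k_dEr = k_dEr, k_dEi = k_dEi,
                 k_de = k_de, lambda = lambda, mu = mu,
                 D_m = D_m, D_c = D_c, v_f = v_f,
                 n_D_mean = n_D_mean, n_E_mean = n_E_mean,
                 variant = variant, advect_minE = isTRUE(advect_minE)),
            class = "min_params")
}

#' @export
print.min_params <- function(x, ...) {
  cat("Min model parameters (variant:", x$variant, ")\n")
  cat(sprintf("  rates [1/s or um^2/s]: k_D=%g k_dD=%g k_dEr=%g k_dEi=%g k_de=%g lambda=%g mu=%g\n",
              x$k_D, x$k_dD, x$k_dEr, x$k_dEi, x$k_de, x$lambda, x$mu))
  cat(sprintf("  transport: D_m=%g D_c=%g um^2/s, v_f=%g um/s (MinE advected: %s)\n",
              x$D_m, x$D_c, x$v_f, x$advect_minE))
  cat(sprintf("  totals: n_D=%g n_E=%g /um^2 (E:D = %.3g)\n",
              x$n_D_mean, x$n_E_mean, x$n_E_mean / x$n_D_mean))
  invisible(x)
}

#' Registry of named kinetic parameter sets
#'
#' Every simulation names the parameter set it was run with, so results are
#' reproducible and parameter provenance is explicit.  The default set,
#' `"invitro_switch_v1"`, describes the in vitro Min system on a supported
#' lipid bilayer in the vertically integrated (2D) geometry.  Its rate
#' constants are adapted from the published switch-model kinetics of the
#' MinE reactive/latent cycle, rescaled by the bulk-gradient penetration
#' depth that the 2D reduction integrates out; the calibration is documented
#' in the methods vignette.
#'
#' @param name name of a registered set.
#' @param ... overrides passed on to the `min_params` fields (e.g. `v_f`,
#'   `n_E_mean`, `variant`).
#' @return `min_param_sets()` returns the names of registered sets;
#'   `min_param_set()` returns a `min_params` object.
#' @export
min_param_set <- function(name = "invitro_switch_v1", ...) {
  sets <- .min_registry()
  if (!name %in% names(sets))
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  args <- sets[[name]]
  over <- list(...)
  bad <- setdiff(names(over), c(names(args), "variant", "advect_minE"))
  if (length(bad)) stop("unknown parameter override(s): ",
                        paste(bad, collapse = ", "))
  args[names(over)] <- over
  ps <- do.call(min_params, args)
  attr(ps, "set_name") <- name
  ps
}

#' @rdname min_param_set
#' @export
min_param_sets <- function() names(.min_registry())

.min_registry <- function() {
  list(
    # Default in vitro switch-model kinetics, 2D-reduced (see vignette).
    invitro_switch_v1 = list(
      k_D = 0.0158, k_dD = 0.00163, k_dEr = 1.18, k_dEi = 0.0005,
      k_de = 0.0963, lambda = 0.562, mu = 2.29,
      D_m = 0.25, D_c = 56, v_f = 0,
      n_D_mean = 638, n_E_mean = 383, variant = "full", advect_minE = TRUE)
  )
}

#' Convenience: parameter set at a given E:D ratio
#'
#' Returns the named set with `n_E_mean` set to `ratio * n_D_mean`, keeping
#' total MinD fixed — the protocol used for all E:D sweeps.
#'
#' @param ratio target MinE:MinD total-density ratio.
#' @param v_f bulk flow velocity (um/s).
#' @param name parameter set name.
#' @param ... further overrides.
#' @export
min_params_at_ratio <- function(ratio, v_f = 0, name = "invitro_switch_v1",
                                ...) {
  base <- min_param_set(name)
  min_param_set(name, n_E_mean = ratio * base$n_D_mean, v_f = v_f, ...)
}

#' Switch a parameter object to another model variant
#'
#' `as_skeleton()` removes the MinE switch (`mu = 0`, latent pool empty).
#' `reduce_switch_model()` builds the reduced switch model: the high-E:D,
#' fast-switching limit in which the bulk MinE fields are eliminated by a
#' quasi-steady-state approximation and replaced by spatially uniform pools
#' slaved to the instantaneous global membrane state through MinE mass
#' conservation.  Only `m_d`, `m_de`, `c_DD`, `c_DT` remain dynamical.
#'
#' @param params a `min_params` object (full variant).
#' @return a `min_params` object of the requested variant.
#' @export
reduce_switch_model <- function(params) {
  stopifnot(inherits(params, "min_params"))
  if (params$n_E_mean <= 0)
    stop("reduced switch model is degenerate at n_E_mean = 0")
  params$variant <- "reduced_switch"
  params
}

#' @rdname reduce_switch_model
#' @export
as_skeleton <- function(params) {
  stopifnot(inherits(params, "min_params"))
  params$variant <- "skeleton"
  params$mu <- 0
  params
}

# field layout shared across the package
.min_fields <- c("m_d", "m_de", "c_DD", "c_DT", "c_Er", "c_Ei")

#' Construct a field state
#'
#' A `field_state` holds the six concentration fields on the lateral grid at
#' one time: membrane MinD (`m_d`), membrane MinDE (`m_de`), bulk MinD-ADP
#' (`c_DD`), bulk MinD-ATP (`c_DT`), reactive bulk MinE (`c_Er`) and latent
#' bulk MinE (`c_Ei`), all as vertically integrated areal densities.
#'
#' @param fields numeric matrix, one column per field in the order
#'   `m_d, m_de, c_DD, c_DT, c_Er, c_Ei`, one row per grid point; or a named
#'   list of equal-length vectors.
#' @param t time (s).
#' @export
field_state <- function(fields, t = 0) {
  if (is.list(fields) && !is.matrix(fields)) {
    stopifnot(all(.min_fields %in% names(fields)))
    fields <- do.call(cbind, fields[.min_fields])
  }
  fields <- as.matrix(fields)
  if (ncol(fields) != 6) stop("state needs 6 field columns")
  colnames(fields) <- .min_fields
  if (any(!is.finite(fields))) stop("non-finite field values")
  structure(list(fields = fields, t = t), class = "field_state")
}

#' Uniform lateral grid with periodic boundaries
#'
#' @param L domain length (um).
#' @param N number of grid points.
#' @export
min_grid <- function(L, N) {
  stopifnot(L > 0, N >= 4)
  structure(list(n_dims = 1L, L = L, N = as.integer(N), dx = L / N,
                 x = seq(0, L, length.out = N + 1)[seq_len(N)]),
            class = "min_grid")
}

#' Reaction fluxes of the Min kinetics
#'
#' Evaluates the mass-action reaction terms at every grid point: basal and
#' self-recruited MinD attachment, MinE recruitment into the MinDE complex,
#' complex detachment, nucleotide exchange (ADP -> ATP at rate `lambda`) and
#' MinE conformational switching (reactive -> latent at rate `mu`).  The
#' returned columns are the full right-hand sides of the reaction part of
#' the dynamics, including the exchange and switching transfer terms, so the
#' MinD columns and the MinE columns each sum to zero pointwise.
#'
#' @param state a `field_state`.
#' @param params a `min_params`.
#' @param tol negative-concentration tolerance; inputs below `-tol` are
#'   rejected.
#' @return matrix with columns `f_d, f_de, f_DD, f_DT, f_Er, f_Ei`.
#' @export
reaction_fluxes <- function(state, params, tol = 1e-9) {
  stopifnot(inherits(state, "field_state"), inherits(params, "min_params"))
  f <- state$fields
  scale <- params$n_D_mean + params$n_E_mean
  if (min(f) < -tol * scale)
    stop("negative concentrations beyond tolerance")
  if (params$variant == "skeleton" && max(abs(f[, "c_Ei"])) > tol * scale)
    stop("skeleton variant requires c_Ei identically zero")
  mu <- if (params$variant == "skeleton") 0 else params$mu
  m_d <- f[, 1]; m_de <- f[, 2]; c_DD <- f[, 3]; c_DT <- f[, 4]
  c_Er <- f[, 5]; c_Ei <- f[, 6]
  attach <- (params$k_D + params$k_dD * m_d) * c_DT
  recr <- (params$k_dEr * c_Er + params$k_dEi * c_Ei) * m_d
  out <- cbind(
    f_d  = attach - recr,
    f_de = recr - params$k_de * m_de,
    f_DD = params$k_de * m_de - params$lambda * c_DD,
    f_DT = -attach + params$lambda * c_DD,
    f_Er = -params$k_dEr * m_d * c_Er + params$k_de * m_de - mu * c_Er,
    f_Ei = -params$k_dEi * m_d * c_Ei + mu * c_Er)
  out
}

#' Conserved total densities
#'
#' Spatial means (not integrals, so values are comparable across grid
#' sizes) of total MinD, `m_d + m_de + c_DD + c_DT`, and total MinE,
#' `m_de + c_Er + c_Ei`.
#'
#' @param state a `field_state`.
#' @param grid optional `min_grid`; used only for a shape check.
#' @return named vector `c(n_D, n_E)`.
#' @export
total_densities <- function(state, grid = NULL) {
  f <- state$fields
  if (!is.null(grid) && nrow(f) != grid$N)
    stop("state/grid shape mismatch")
  c(n_D = mean(f[, 1] + f[, 2] + f[, 3] + f[, 4]),
    n_E = mean(f[, 2] + f[, 5] + f[, 6]))
}

#' Homogeneous steady state of the well-mixed kinetics
#'
#' Finds the spatially uniform fixed point with the prescribed total
#' densities.  Conservation and the steady-state conditions reduce the
#' problem to a single scalar root equation in the membrane MinD density
#' `m_d`: all other concentrations follow in closed form.  If several roots
#' exist, the one reached by relaxing the well-mixed rate equations from the
#' uniform partition (all MinD as `c_DT`, all MinE as `c_Er`) is returned.
#'
#' @param params a `min_params`.
#' @param grid optional `min_grid`; if given, the state is replicated on it,
#'   otherwise a single-point state is returned.
#' @param tol residual tolerance on the reaction fluxes.
#' @return a uniform `field_state` with `attr(, "residual")`.
#' @export
homogeneous_steady_state <- function(params, grid = NULL, tol = 1e-10) {
  stopifnot(inherits(params, "min_params"))
  n_D <- params$n_D_mean; n_E <- params$n_E_mean
  mu <- if (params$variant == "skeleton") 0 else params$mu

  if (n_E == 0) {
    # no detachment pathway: all MinD ends membrane-bound
    u <- c(m_d = n_D, m_de = 0, c_DD = 0, c_DT = 0, c_Er = 0, c_Ei = 0)
    return(.uniform_state(u, params, grid))
  }

  if (params$variant == "reduced_switch") {
    # the slaved pools obey c_Er = k_de m_de/(k_dEr m_d + mu) and
    # c_Ei = n_E - m_de - c_Er; the fixed point balances recruitment
    # against detachment and conserves MinD
    mde_of_r <- function(m_d) {
      bal <- function(m_de) {
        c_Er <- params$k_de * m_de / (params$k_dEr * m_d + mu)
        c_Ei <- max(0, n_E - m_de - c_Er)
        (params$k_dEr * c_Er + params$k_dEi * c_Ei) * m_d -
          params$k_de * m_de
      }
      stats::uniroot(bal, c(n_E * 1e-12, n_E), tol = 1e-14)$root
    }
    gr <- function(m_d) {
      m_de <- mde_of_r(m_d)
      m_d + m_de + params$k_de * m_de / params$lambda +
        params$k_de * m_de / (params$k_D + params$k_dD * m_d) - n_D
    }
    ms <- exp(seq(log(n_D * 1e-10), log(n_D), length.out = 200))
    gv <- vapply(ms, gr, numeric(1))
    sc <- which(diff(sign(gv)) != 0)
    if (!length(sc)) stop("reduced-model steady-state search failed")
    m_d <- stats::uniroot(gr, c(ms[sc[1]], ms[sc[1] + 1]), tol = 1e-14)$root
    m_de <- mde_of_r(m_d)
    c_Er <- params$k_de * m_de / (params$k_dEr * m_d + mu)
    u <- c(m_d = m_d, m_de = m_de,
           c_DD = params$k_de * m_de / params$lambda,
           c_DT = params$k_de * m_de / (params$k_D + params$k_dD * m_d),
           c_Er = c_Er, c_Ei = max(0, n_E - m_de - c_Er))
    st <- .uniform_state(u, params, grid)
    attr(st, "residual") <- NA_real_
    return(st)
  }

  # closed-form slaving: given m_d, steady state gives
  #   c_Er = k_de m_de / (k_dEr m_d + mu)
  #   c_Ei = mu c_Er / (k_dEi m_d)           (0 when mu = 0)
  #   c_DD = k_de m_de / lambda
  #   c_DT = k_de m_de / (k_D + k_dD m_d)
  # and MinE conservation fixes m_de(m_d).
  mde_of <- function(m_d) {
    den <- 1 + params$k_de / (params$k_dEr * m_d + mu) *
      (1 + if (mu > 0) mu / (params$k_dEi * m_d) else 0)
    n_E / den
  }
  gfun <- function(m_d) {
    m_de <- mde_of(m_d)
    m_d + m_de + params$k_de * m_de / params$lambda +
      params$k_de * m_de / (params$k_D + params$k_dD * m_d) - n_D
  }

  # bracket roots on (0, n_D]
  lo <- n_D * 1e-12
  ms <- exp(seq(log(lo), log(n_D), length.out = 400))
  gv <- vapply(ms, gfun, numeric(1))
  sc <- which(diff(sign(gv)) != 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(gfun, c(ms[i], ms[i + 1]), tol = 1e-14)$root, numeric(1))
  if (!length(roots))
    stop("steady-state root search failed to converge; g-range [",
         signif(min(gv), 3), ", ", signif(max(gv), 3), "]")

  build <- function(m_d) {
    m_de <- mde_of(m_d)
    c_Er <- params$k_de * m_de / (params$k_dEr * m_d + mu)
    c_Ei <- if (mu > 0) mu * c_Er / (params$k_dEi * m_d) else 0
    c(m_d = m_d, m_de = m_de, c_DD = params$k_de * m_de / params$lambda,
      c_DT = params$k_de * m_de / (params$k_D + params$k_dD * m_d),
      c_Er = c_Er, c_Ei = c_Ei)
  }

  if (length(roots) > 1L) {
    relax <- .well_mixed_relax(params)
    pick <- which.min(abs(roots - relax["m_d"]))
    u <- build(roots[pick])
  } else {
    u <- build(roots)
  }

  st <- .uniform_state(u, params, grid)
  res <- max(abs(reaction_fluxes(st, params)))
  if (res > tol * max(1, n_D))
    stop("steady-state residual ", signif(res, 3), " above tolerance")
  attr(st, "residual") <- res
  st
}

# long-time limit of the zero-gradient (well-mixed) rate equations,
# started from the uniform partition
.well_mixed_relax <- function(params, t_end = 2e4) {
  y0 <- c(m_d = 0, m_de = 0, c_DD = 0, c_DT = params$n_D_mean,
          c_Er = params$n_E_mean, c_Ei = 0)
  rhs <- function(t, y, p) {
    st <- field_state(matrix(y, nrow = 1,
                             dimnames = list(NULL, .min_fields)), t)
    list(as.numeric(reaction_fluxes(st, params, tol = 1e-6)))
  }
  out <- deSolve::ode(y0, times = c(0, t_end / 10, t_end), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  out[nrow(out), -1]
}

.uniform_state <- function(u, params, grid) {
  n <- if (is.null(grid)) 1L else grid$N
  field_state(matrix(rep(u, each = n), nrow = n,
                     dimnames = list(NULL, .min_fields)), t = 0)
}
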
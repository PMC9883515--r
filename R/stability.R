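#' Reaction Jacobian at a uniform state
#'
#' Analytic 6x6 Jacobian of the reaction terms, ordered
#' `(m_d, m_de, c_DD, c_DT, c_Er, c_Ei)`.
#'
#' @param params a `min_params` (full or skeleton variant).
#' @param steady a uniform `field_state` (only the first row is used).
#' @return real 6x6 matrix.
#' @export
reaction_jacobian <- function(params, steady) {
  u <- steady$fields[1, ]
  mu <- if (params$variant == "skeleton") 0 else params$mu
  m_d <- u[1]; c_DT <- u[4]; c_Er <- u[5]; c_Ei <- u[6]
  kD <- params$k_D; kdD <- params$k_dD; kEr <- params$k_dEr
  kEi <- params$k_dEi; kde <- params$k_de; lam <- params$lambda
  a <- kD + kdD * m_d
  J <- matrix(0, 6, 6, dimnames = list(.min_fields, .min_fields))
  J[1, ] <- c(kdD * c_DT - kEr * c_Er - kEi * c_Ei, 0, 0, a,
              -kEr * m_d, -kEi * m_d)
  J[2, ] <- c(kEr * c_Er + kEi * c_Ei, -kde, 0, 0, kEr * m_d, kEi * m_d)
  J[3, ] <- c(0, kde, -lam, 0, 0, 0)
  J[4, ] <- c(-kdD * c_DT, 0, lam, -a, 0, 0)
  J[5, ] <- c(-kEr * c_Er, kde, 0, 0, -kEr * m_d - mu, 0)
  J[6, ] <- c(-kEi * c_Ei, 0, 0, 0, mu, -kEi * m_d)
  J
}

#' Linearized operator at lateral wavenumber q
#'
#' For perturbations proportional to `exp(i q x + sigma t)` about the
#' homogeneous steady state,
#' `J(q) = R - q^2 diag(D_m, D_m, D_c, D_c, D_c, D_c)
#'         - i q v_f diag(0, 0, 1, 1, a, a)`
#' with `a = 1` if bulk MinE is advected and 0 otherwise, and `R` the
#' reaction Jacobian.
#'
#' @param params a `min_params`.
#' @param steady uniform `field_state`; must be a fixed point (residual of
#'   [reaction_fluxes()] below `tol`).
#' @param q lateral wavenumber (1/um).
#' @param tol fixed-point residual tolerance.
#' @return complex 6x6 matrix.
#' @export
jacobian_at_q <- function(params, steady, q, tol = 1e-6) {
  if (params$variant == "reduced_switch")
    stop("the reduced switch model has global coupling; its linearization ",
         "is not a local 6x6 operator")
  res <- max(abs(reaction_fluxes(steady, params)))
  if (res > tol * max(1, params$n_D_mean))
    stop("steady-state residual ", signif(res, 3), " above tolerance")
  R <- reaction_jacobian(params, steady)
  a <- if (params$advect_minE) 1 else 0
  D <- c(params$D_m, params$D_m, rep(params$D_c, 4))
  adv <- c(0, 0, 1, 1, a, a)
  R - q^2 * diag(D) - 1i * q * params$v_f * diag(adv)
}

#' Dispersion relation about the homogeneous steady state
#'
#' Eigenvalues of the linearized operator over a wavenumber grid.  Branches
#' are tracked by eigenvector overlap between adjacent `q` points; the
#' leading growth rate `sigma(q)` is the eigenvalue with the largest real
#' part at each `q`.  Sign convention: perturbations go as
#' `exp(i q x + sigma t)`, so the phase velocity is `-Im sigma / q` and
#' "downstream" means the phase velocity has the sign of `v_f`.
#'
#' @param params a `min_params`.
#' @param q_grid wavenumbers (1/um); 0 is allowed.
#' @param steady optional precomputed steady state.
#' @return object of class `dispersion_relation`: list with `q`, `sigma`
#'   (leading, complex), `branches` (complex matrix, q x 6, overlap-tracked)
#'   and `params`.
#' @export
dispersion_relation <- function(params, q_grid, steady = NULL) {
  if (is.null(steady)) steady <- homogeneous_steady_state(params)
  nq <- length(q_grid)
  branches <- matrix(NA_complex_, nq, 6)
  lead <- complex(nq)
  prev_vec <- NULL
  for (i in seq_len(nq)) {
    eg <- eigen(jacobian_at_q(params, steady, q_grid[i]))
    val <- eg$values; vec <- eg$vectors
    if (!is.null(prev_vec)) {
      # greedy assignment maximizing |<v_prev, v>| per branch
      ov <- abs(Conj(t(prev_vec)) %*% vec)
      ord <- integer(6); taken <- rep(FALSE, 6)
      for (b in seq_len(6)) {
        j <- which.max(ifelse(taken, -1, ov[b, ]))
        ord[b] <- j; taken[j] <- TRUE
      }
      val <- val[ord]; vec <- vec[, ord, drop = FALSE]
    } else {
      o <- order(-Re(val)); val <- val[o]; vec <- vec[, o, drop = FALSE]
    }
    branches[i, ] <- val
    lead[i] <- val[which.max(Re(val))]
    prev_vec <- vec
  }
  structure(list(q = q_grid, sigma = lead, branches = branches,
                 params = params, steady = steady),
            class = "dispersion_relation")
}

#' Unstable wavenumber bands
#'
#' Contiguous intervals of `Re sigma(q) > 0` (for `q > 0`), each summarized
#' by its edges, the fastest-growing wavenumber `q_peak` (parabolic
#' refinement), the phase velocity `-Im sigma(q_peak)/q_peak` and a
#' direction label: `"downstream"` if the phase velocity has the sign of
#' `v_f`, `"upstream"` if opposite, `"none"` at `v_f = 0`.
#'
#' @param disp a `dispersion_relation`.
#' @return data frame, one row per band (zero rows if stable).
#' @export
instability_bands <- function(disp) {
  pos <- disp$q > 1e-12
  q <- disp$q[pos]; s <- disp$sigma[pos]
  un <- Re(s) > 0
  out <- data.frame(q_min = numeric(0), q_peak = numeric(0),
                    q_max = numeric(0), growth = numeric(0),
                    phase_velocity = numeric(0), direction = character(0))
  if (!any(un)) return(out)
  r <- rle(un)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  v_f <- disp$params$v_f
  for (b in which(r$values)) {
    i0 <- starts[b]; i1 <- ends[b]
    # interpolated zero crossings of Re sigma
    q_lo <- if (i0 > 1)
      q[i0 - 1] + (q[i0] - q[i0 - 1]) *
        (-Re(s[i0 - 1])) / (Re(s[i0]) - Re(s[i0 - 1])) else q[i0]
    q_hi <- if (i1 < length(q))
      q[i1] + (q[i1 + 1] - q[i1]) *
        Re(s[i1]) / (Re(s[i1]) - Re(s[i1 + 1])) else q[i1]
    ip <- i0 - 1 + which.max(Re(s[i0:i1]))
    qp <- q[ip]; gp <- Re(s[ip]); imp <- Im(s[ip])
    if (ip > i0 && ip < i1) {  # parabolic peak refinement
      y <- Re(s[(ip - 1):(ip + 1)])
      d <- (y[1] - y[3]) / (2 * (y[1] - 2 * y[2] + y[3]))
      if (is.finite(d) && abs(d) < 1) {
        qp <- q[ip] + d * (q[ip + 1] - q[ip])
        gp <- y[2] - 0.25 * (y[1] - y[3]) * d
        imp <- stats::approx(q[(ip - 1):(ip + 1)],
                             Im(s[(ip - 1):(ip + 1)]), xout = qp)$y
      }
    }
    vph <- -imp / qp
    dir <- if (v_f == 0) "none"
           else if (abs(vph) < 1e-12) "stationary"
           else if (sign(vph) == sign(v_f)) "downstream" else "upstream"
    out <- rbind(out, data.frame(q_min = q_lo, q_peak = qp, q_max = q_hi,
                                 growth = gp, phase_velocity = vph,
                                 direction = dir))
  }
  out
}

#' Critical flow velocity of the flow-driven instability
#'
#' For a parameter point that is laterally stable without flow, finds the
#' smallest flow speed at which the homogeneous steady state loses lateral
#' stability (`max_q Re sigma > 0`), scanning `v_grid` and refining by
#' bisection.  The threshold is invariant under the sign of `v_f`.
#'
#' @param params a `min_params`; must satisfy `max_q Re sigma(q) < 0` at
#'   `v_f = 0`.
#' @param v_grid increasing flow speeds to scan (um/s).
#' @param q_grid wavenumbers used for the stability scan.
#' @param tol bisection tolerance on the threshold (um/s).
#' @return critical speed (um/s), or `NA` with a message if stable over the
#'   whole grid.
#' @export
flow_driven_threshold <- function(params, v_grid,
                                  q_grid = seq(0.005, 1.5, length.out = 160),
                                  tol = 1e-3) {
  maxRe <- function(v) {
    p <- params; p$v_f <- v
    ss <- homogeneous_steady_state(p)
    max(Re(dispersion_relation(p, q_grid, ss)$sigma))
  }
  g0 <- maxRe(0)
  if (g0 >= 0)
    stop("point is already laterally unstable at v_f = 0 (max Re sigma = ",
         signif(g0, 3), ")")
  v_grid <- sort(abs(v_grid))
  gs <- vapply(v_grid, maxRe, numeric(1))
  i <- which(gs > 0)[1]
  if (is.na(i)) {
    message("laterally stable over the whole velocity grid")
    return(NA_real_)
  }
  lo <- if (i > 1) v_grid[i - 1] else 0
  hi <- v_grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (maxRe(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
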
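test_that("reaction Jacobian matches numerical differentiation", {
  p <- test_params_ratio(0.5, v_f = 1.5)
  ss <- homogeneous_steady_state(p)
  J <- reaction_jacobian(p, ss)
  u0 <- ss$fields[1, ]
  h <- 1e-5 * max(u0)
  Jnum <- matrix(0, 6, 6)
  for (j in 1:6) {
    up <- u0; up[j] <- up[j] + h
    dn <- u0; dn[j] <- dn[j] - h
    fp <- reaction_fluxes(field_state(matrix(up, 1)), p)
    fm <- reaction_fluxes(field_state(matrix(dn, 1)), p)
    Jnum[, j] <- (fp - fm) / (2 * h)
  }
  expect_equal(unname(J), Jnum, tolerance = 1e-6)
})

test_that("q = 0 carries exactly two zero modes from the conservation laws", {
  for (variant in c("full", "skeleton")) for (v in c(0, 4)) {
    p <- test_params_ratio(0.4, v_f = v, variant = variant)
    ss <- homogeneous_steady_state(p)
    ev <- eigen(jacobian_at_q(p, ss, 0), only.values = TRUE)$values
    n_zero <- sum(abs(ev) < 1e-10)
    expect_equal(n_zero, 2)
  }
})

test_that("the linear operator is real without flow and conjugate-mirrored
           with it", {
  p0 <- test_params_ratio(0.5)
  ss <- homogeneous_steady_state(p0)
  J <- jacobian_at_q(p0, ss, 0.2)
  expect_equal(max(abs(Im(J))), 0)

  pv <- test_params_ratio(0.5, v_f = 2)
  pm <- test_params_ratio(0.5, v_f = -2)
  sv <- homogeneous_steady_state(pv)
  sp <- sort_complex <- function(z) z[order(Re(z), Im(z))]
  e1 <- eigen(jacobian_at_q(pv, sv, 0.2), only.values = TRUE)$values
  e2 <- eigen(jacobian_at_q(pm, sv, 0.2), only.values = TRUE)$values
  expect_equal(sp(Conj(e1)), sp(e2), tolerance = 1e-10)

  # at v_f = 0 the dispersion relation is symmetric in q
  d <- dispersion_relation(p0, c(-0.3, 0.3), ss)
  expect_equal(Re(d$sigma[1]), Re(d$sigma[2]), tolerance = 1e-10)
})

test_that("the steady state must be a fixed point and the reduced model is
           rejected", {
  p <- test_params_ratio(0.5)
  bad <- homogeneous_steady_state(p)
  bad$fields <- bad$fields * 1.05
  expect_error(jacobian_at_q(p, bad, 0.1), "residual")
  pr <- reduce_switch_model(test_params_ratio(1))
  ssr <- homogeneous_steady_state(pr)
  expect_error(jacobian_at_q(pr, ssr, 0.1), "global")
})

test_that("skeleton dispersion equals full-model dispersion at mu = 0", {
  qg <- seq(0.02, 0.8, length.out = 25)
  pf <- test_params_ratio(0.3, mu = 0)
  pk <- as_skeleton(test_params_ratio(0.3))
  df <- dispersion_relation(pf, qg)
  dk <- dispersion_relation(pk, qg)
  expect_equal(df$sigma, dk$sigma, tolerance = 1e-8)
})

test_that("instability bands report edges, peak and direction labels", {
  p <- test_params_ratio(0.6, v_f = 2)
  d <- dispersion_relation(p, seq(0.01, 1, length.out = 120))
  b <- instability_bands(d)
  expect_gt(nrow(b), 0)
  expect_true(all(b$q_min < b$q_peak & b$q_peak < b$q_max))
  expect_true(all(b$direction %in% c("upstream", "downstream", "stationary")))
  # without flow there is no direction label
  p0 <- test_params_ratio(0.6)
  b0 <- instability_bands(dispersion_relation(p0,
                                              seq(0.01, 1, length.out = 80)))
  expect_true(all(b0$direction == "none"))
})

test_that("flow-driven threshold demands a stable point and is sign
           invariant", {
  # already unstable without flow: precondition violated
  p_hi <- test_params_ratio(0.6)
  expect_error(flow_driven_threshold(p_hi, c(1, 2)), "already")

  p_lo <- test_params_ratio(0.05)
  qg <- seq(0.005, 0.8, length.out = 80)
  v1 <- flow_driven_threshold(p_lo, c(0.25, 0.5, 1, 2, 4), q_grid = qg,
                              tol = 0.02)
  v2 <- flow_driven_threshold(p_lo, -c(0.25, 0.5, 1, 2, 4), q_grid = qg,
                              tol = 0.02)
  expect_true(is.finite(v1))
  expect_equal(v1, v2, tolerance = 1e-12)
})
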
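test_that("reaction fluxes implement the attachment/detachment kinetics", {
  p <- test_params()
  g <- small_grid(N = 8)

  zero <- field_state(matrix(0, 8, 6))
  expect_equal(unname(reaction_fluxes(zero, p)), matrix(0, 8, 6))

  # only basal attachment active: m_d = 0, c_DT = 1
  f <- matrix(0, 8, 6); f[, 4] <- 1
  fx <- reaction_fluxes(field_state(f), p)
  expect_equal(unname(fx[, "f_d"]), rep(p$k_D, 8))
  expect_equal(unname(fx[, "f_DT"]), rep(-p$k_D, 8))
  expect_equal(max(abs(fx[, c("f_de", "f_DD", "f_Er", "f_Ei")])), 0)
})

test_that("reaction fluxes conserve MinD and MinE pointwise", {
  g <- small_grid(N = 32)
  for (variant in c("full", "skeleton")) {
    p <- test_params(variant = variant)
    st <- random_state(p, g, seed = 7)
    fx <- reaction_fluxes(st, p)
    minD <- fx[, "f_d"] + fx[, "f_de"] + fx[, "f_DD"] + fx[, "f_DT"]
    minE <- fx[, "f_de"] + fx[, "f_Er"] + fx[, "f_Ei"]
    expect_lt(max(abs(minD)), 1e-10)
    expect_lt(max(abs(minE)), 1e-10)
  }
})

test_that("negative inputs beyond tolerance are rejected", {
  p <- test_params()
  f <- matrix(1, 4, 6); f[2, 3] <- -1
  expect_error(reaction_fluxes(field_state(f), p), "negative")
})

test_that("total densities are means of the species sums", {
  g <- small_grid(N = 16)
  st <- field_state(matrix(1, 16, 6))
  expect_equal(total_densities(st, g), c(n_D = 4, n_E = 3))

  # empty MinE pools: n_E reduces to mean(m_de)
  f <- matrix(0, 16, 6); f[, 2] <- 2.5; f[, 1] <- 1
  expect_equal(total_densities(field_state(f))[["n_E"]], 2.5)
  expect_error(total_densities(st, min_grid(10, 8)), "mismatch")
})

test_that("homogeneous steady state is a root of the kinetics with the
           prescribed totals", {
  for (ratio in c(0.05, 0.3, 1)) {
    p <- test_params_ratio(ratio)
    ss <- homogeneous_steady_state(p)
    expect_lt(max(abs(reaction_fluxes(ss, p))), 1e-8)
    td <- total_densities(ss)
    expect_equal(td[["n_D"]], p$n_D_mean, tolerance = 1e-9)
    expect_equal(td[["n_E"]], p$n_E_mean, tolerance = 1e-9)
    expect_true(all(ss$fields >= 0))
  }
})

test_that("MinE-free steady state puts all MinD on the membrane", {
  p <- test_params(n_E_mean = 0)
  ss <- homogeneous_steady_state(p)
  u <- ss$fields[1, ]
  expect_equal(u[["m_d"]], p$n_D_mean)
  expect_equal(max(abs(u[c("m_de", "c_Er", "c_Ei", "c_DT", "c_DD")])), 0)
  expect_lt(max(abs(reaction_fluxes(ss, p))), 1e-10)
})

test_that("steady state matches the long-time well-mixed relaxation", {
  p <- test_params_ratio(0.5)
  ss <- homogeneous_steady_state(p)
  relax <- minflow:::.well_mixed_relax(p)
  expect_equal(unname(ss$fields[1, ]), unname(relax), tolerance = 1e-6)
})

test_that("skeleton variant forces mu = 0 and rejects latent MinE", {
  p <- as_skeleton(test_params(mu = 3))
  expect_equal(p$mu, 0)
  f <- matrix(1, 4, 6)
  expect_error(reaction_fluxes(field_state(f), p), "c_Ei")
})

test_that("reduced switch model rejects the MinE-free limit and keeps a
           consistent steady state", {
  expect_error(reduce_switch_model(test_params(n_E_mean = 0)), "degenerate")
  p <- reduce_switch_model(test_params_ratio(1))
  ss <- homogeneous_steady_state(p)
  td <- total_densities(ss)
  expect_equal(td[["n_D"]], p$n_D_mean, tolerance = 1e-8)
  expect_equal(td[["n_E"]], p$n_E_mean, tolerance = 1e-8)
  # slaved reactive pool obeys the quasi-steady-state balance
  u <- ss$fields[1, ]
  expect_equal(u[["c_Er"]],
               p$k_de * u[["m_de"]] / (p$k_dEr * u[["m_d"]] + p$mu),
               tolerance = 1e-8)
})

test_that("parameter registry validates overrides and invariants", {
  expect_true("invitro_switch_v1" %in% min_param_sets())
  expect_error(min_param_set("no_such_set"), "unknown parameter set")
  expect_error(min_param_set(k_qq = 1), "unknown parameter override")
  expect_error(min_params(k_D = -1, k_dD = 0, k_dEr = 0, k_dEi = 0,
                          k_de = 0, lambda = 0, mu = 0, D_m = 0, D_c = 0,
                          n_D_mean = 1, n_E_mean = 0), ">= 0")
  p <- min_params_at_ratio(0.25, v_f = 2)
  expect_equal(p$n_E_mean / p$n_D_mean, 0.25)
  expect_equal(p$v_f, 2)
})
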
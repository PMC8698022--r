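test_that("cross_params_lb satisfies the self-combination identity", {
  crit <- critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25, omega = 0.5)
  cc <- cross_params_lb(crit, crit, k12 = 0)
  expect_equal(cc$Tc, crit$Tc)
  expect_equal(cc$Vc, crit$Vc)
  expect_equal(cc$Zc, crit$Zc)
  expect_equal(cc$Pc, crit$Zc * R_GAS * crit$Tc / crit$Vc)
})

test_that("cross_params_lb degenerates to zero attraction at k12 = 1", {
  cc <- cross_params_lb(co2_critical(),
                        critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25),
                        k12 = 1)
  expect_identical(cc$Tc, 0)
  expect_identical(cc$aij, 0)
})

test_that("cross_params_lb matches hand arithmetic and is symmetric", {
  co2 <- co2_critical()
  sol <- critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25, omega = 0.5)
  cc <- cross_params_lb(co2, sol, k12 = 0.1)
  Tcij <- (1 - 0.1) * sqrt(co2$Tc * 700)
  Vcij <- ((co2$Vc^(1 / 3) + (6e-4)^(1 / 3)) / 2)^3
  Zcij <- (co2$Zc + 0.25) / 2
  Pcij <- Zcij * R_GAS * Tcij / Vcij
  expect_equal(cc$Tc, Tcij, tolerance = 1e-12)
  expect_equal(cc$Vc, Vcij, tolerance = 1e-12)
  expect_equal(cc$Pc, Pcij, tolerance = 1e-12)
  expect_equal(cc$aij, 0.42748 * R_GAS^2 * Tcij^2.5 / Pcij, tolerance = 1e-12)
  expect_equal(cross_params_lb(sol, co2, 0.1), cc, tolerance = 1e-12)
})

test_that("mix_vdw honors the pure limits and midpoint arithmetic", {
  expect_equal(mix_vdw(0, 1, 2, 3, 1, 3), list(a = 1, b = 1))
  expect_equal(mix_vdw(1, 1, 2, 3, 1, 3), list(a = 3, b = 3))
  expect_equal(mix_vdw(0.5, 1, 2, 3, 1, 3), list(a = 2, b = 2))
  expect_error(mix_vdw(1.5, 1, 2, 3, 1, 3), "y2")
})

test_that("phi2_classical approaches 1 in the ideal-gas limit", {
  sol <- critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25, omega = 0.5)
  for (nm in c("rk", "srk", "pr")) {
    phi <- phi2_classical(nm, 313.15, 1, 1e-6, co2_critical(), sol,
                          k12 = 0.1, rule = "lorentz_berthelot")
    expect_equal(phi, 1, tolerance = 1e-5)
  }
})

test_that("phi2_classical matches quadrature of the defining integral", {
  set.seed(7)
  co2 <- co2_critical()
  for (i in 1:5) {
    nm <- sample(c("rk", "srk", "pr"), 1)
    eos <- eos_form(nm)
    sol <- random_solute_crit()
    T <- runif(1, 308, 340)
    P <- runif(1, 8e6, 30e6)
    y2 <- runif(1, 1e-6, 5e-4)
    k12 <- runif(1, -0.1, 0.2)
    phi <- phi2_classical(eos, T, P, y2, co2, sol, k12, "van_der_waals")
    p1 <- pure_params(eos, co2, T)
    p2 <- pure_params(eos, sol, T)
    a12 <- (1 - k12) * sqrt(p1$a * p2$a)
    lnphi_q <- phi2_quadrature_oracle(eos, T, P, y2, p1$a, a12, p2$a,
                                      p1$b, p2$b)
    expect_equal(phi, exp(lnphi_q), tolerance = 1e-6)
  }
})

test_that("phi2 is positive and finite over a state sweep", {
  co2 <- co2_critical()
  sol <- critical_set(Tc = 750, Vc = 5e-4, Zc = 0.24, omega = 0.6)
  for (T in c(310, 325, 340)) for (P in c(9e6, 2e7, 3.4e7)) {
    phi <- phi2_classical("pr", T, P, 1e-5, co2, sol, 0.08,
                          "lorentz_berthelot")
    expect_true(is.finite(phi) && phi > 0)
  }
})

test_that("phi2_schmitt_reid reduces to the pure-CO2 PR fugacity when the solute equals the solvent", {
  co2 <- co2_critical()
  for (T in c(310, 330)) for (P in c(1e7, 2.5e7)) {
    p1 <- pure_params("pr", co2, T)
    phi_sr <- phi2_schmitt_reid(T, P, p1, schmitt_reid_params(p1$a, p1$b))
    expect_equal(phi_sr, phi_pure("pr", T, P, co2), tolerance = 1e-12)
  }
})

test_that("phi2_schmitt_reid equals the y2 -> 0 classical PR limit with k12 = 0", {
  set.seed(11)
  co2 <- co2_critical()
  for (i in 1:10) {
    sol <- random_solute_crit()
    T <- runif(1, 308, 340)
    P <- runif(1, 8e6, 3.4e7)
    p2 <- pure_params("pr", sol, T)
    p1 <- pure_params("pr", co2, T)
    phi_sr <- phi2_schmitt_reid(T, P, p1, schmitt_reid_params(p2$a, p2$b))
    phi_cl <- phi2_classical("pr", T, P, 1e-12, co2, sol, k12 = 0,
                             rule = "van_der_waals")
    expect_equal(phi_sr, phi_cl, tolerance = 1e-8)
  }
})

test_that("penicillin-scale Schmitt-Reid parameters give phi2 << 1", {
  # strong solute-solvent attraction drives the large solubility enhancement
  p1 <- pure_params("pr", co2_critical(), 313.15)
  phi <- phi2_schmitt_reid(313.15, 20e6, p1,
                           schmitt_reid_params(12.8, 1.98e-4))
  expect_lt(phi, 1e-2)
  expect_gt(phi, 0)
})
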
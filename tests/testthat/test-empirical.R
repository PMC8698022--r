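# Dataset lying exactly on an MST plane T ln(y2 P) = A + B rho + C T,
# with EoS densities so the pipeline's auto-fill reproduces it.
mst_exact_dataset <- function(A = -9000, B = 3, C = 26) {
  T <- rep(c(313.15, 323.15, 333.15), each = 6)
  P <- rep(c(100, 150, 200, 250, 300, 350), 3)
  rho <- co2_density(T, P * 1e5)
  y2 <- exp((A + B * rho) / T + C) / (P * 1e5)
  solubility_dataset(data.frame(temperature_K = T, pressure_bar = P,
                                y2 = y2, density_kg_m3 = rho))
}

test_that("aard matches hand arithmetic and validates input", {
  expect_identical(aard(c(1e-5, 2e-5), c(1e-5, 2e-5)), 0)
  expect_identical(aard(c(1e-5, 3e-6), 2 * c(1e-5, 3e-6)), 100)
  expect_equal(aard(c(1e-5, 2e-5), c(1.1e-5, 1.8e-5)), 10)
  expect_error(aard(c(1e-5), c(1e-5, 2e-5)), "length")
  expect_error(aard(c(0, 1e-5), c(1e-5, 1e-5)), "positive")
})

test_that("mst_fit recovers a generating plane exactly", {
  ds <- mst_exact_dataset()
  fit <- mst_fit(ds)
  expect_equal(fit$A, -9000, tolerance = 1e-9)
  expect_equal(fit$B, 3, tolerance = 1e-9)
  expect_equal(fit$C, 26, tolerance = 1e-9)
  expect_lt(fit$aard, 1e-8)
})

test_that("mst_fit agrees with an independent normal-equations solve", {
  ds <- add_co2_density(generate_dataset(
    penicillin_fixture("penG", noise_cv = 0.08, seed = 4)))
  fit <- mst_fit(ds)
  T <- ds$temperature_K
  X <- cbind(1, ds$density_kg_m3, T)
  y <- T * log(ds$y2 * ds$pressure_bar * 1e5)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(c(fit$A, fit$B, fit$C), as.numeric(beta), tolerance = 1e-10)
})

test_that("bartle_fit recovers a generating model exactly and dHs = -bR", {
  a <- 23; b <- -9800; cc <- 1.1e-2
  T <- rep(c(313.15, 323.15, 333.15), each = 6)
  P <- rep(c(100, 150, 200, 250, 300, 350), 3)
  rho <- co2_density(T, P * 1e5)
  y2 <- exp(a + b / T + cc * (rho - 700)) * 1e5 / (P * 1e5)
  ds <- solubility_dataset(data.frame(temperature_K = T, pressure_bar = P,
                                      y2 = y2, density_kg_m3 = rho))
  fit <- bartle_fit(ds)
  expect_equal(fit$a, a, tolerance = 1e-9)
  expect_equal(fit$b, b, tolerance = 1e-9)
  expect_equal(fit$c, cc, tolerance = 1e-9)
  expect_identical(fit$dHs, -fit$b * R_GAS) # definitional, machine-exact
  expect_lt(fit$aard, 1e-8)
})

test_that("mst_fit and bartle_fit are invariant to row order", {
  ds <- add_co2_density(generate_dataset(
    penicillin_fixture("penG", noise_cv = 0.08, seed = 6)))
  perm <- sample(nrow(ds))
  ds_p <- solubility_dataset(as.data.frame(ds)[perm, ])
  m1 <- mst_fit(ds); m2 <- mst_fit(ds_p)
  expect_equal(c(m1$A, m1$B, m1$C, m1$aard),
               c(m2$A, m2$B, m2$C, m2$aard), tolerance = 1e-10)
  b1 <- bartle_fit(ds); b2 <- bartle_fit(ds_p)
  expect_equal(c(b1$a, b1$b, b1$c, b1$aard),
               c(b2$a, b2$b, b2$c, b2$aard), tolerance = 1e-10)
})

test_that("consistency_check flags nothing on exactly collinear data", {
  ds <- mst_exact_dataset()
  cc <- consistency_check(ds)
  expect_identical(sum(cc$flagged), 0L)
  expect_equal(cc$r_squared, 1, tolerance = 1e-10)
})

test_that("an infinite threshold never flags", {
  ds <- add_co2_density(generate_dataset(
    penicillin_fixture("penG", noise_cv = 0.1, seed = 8, outliers = TRUE)))
  cc <- consistency_check(ds, z_threshold = Inf)
  expect_identical(sum(cc$flagged), 0L)
})

test_that("the two constructed off-line points are the only ones flagged", {
  for (cv in c(0, 0.08)) {
    ds <- add_co2_density(generate_dataset(
      penicillin_fixture("penG", noise_cv = cv, seed = 2, outliers = TRUE)))
    cc <- consistency_check(ds)
    expected <- which(ds$temperature_K %in% c(323.15, 333.15) &
                      ds$pressure_bar == 100)
    expect_identical(which(cc$flagged), expected)
  }
})

test_that("estimate_new_psub auto-fills EoS densities when absent", {
  ds <- generate_dataset(penicillin_fixture("penG"))
  expect_false("density_kg_m3" %in% names(ds))
  est <- estimate_new_psub(ds, density_source = "eos")
  est_col <- estimate_new_psub(add_co2_density(ds))
  expect_equal(est$model$AS, est_col$model$AS, tolerance = 1e-12)
  expect_equal(est$model$BS, est_col$model$BS, tolerance = 1e-12)
})

test_that("estimate_new_psub recovers the MST intercept exactly on MST-family data", {
  ds <- mst_exact_dataset(A = -9000, B = 3, C = 26)
  est <- estimate_new_psub(ds)
  expect_length(est$flagged, 0)
  expect_equal(est$model$AS, 26, tolerance = 1e-9)
  expect_gt(est$model$BS, 0)
})

test_that("the estimated model is stable under one extra cleaning pass", {
  ds <- add_co2_density(generate_dataset(
    penicillin_fixture("penG", outliers = TRUE)))
  e1 <- estimate_new_psub(ds)
  expect_identical(e1$flagged, c(7L, 13L))
  e2 <- estimate_new_psub(ds[-e1$flagged, ])
  expect_equal(e2$model$AS, e1$model$AS, tolerance = 0.05)
  expect_equal(e2$model$BS, e1$model$BS, tolerance = 0.05)
})

test_that("estimate_new_psub fails cleanly when too few points survive", {
  ds <- add_co2_density(generate_dataset(penicillin_fixture("penG")))
  expect_error(estimate_new_psub(ds[1:3, ][c(1, 2, 3), ][1:2, ]),
               "3 points")
})
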
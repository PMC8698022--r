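classical_truth <- function() {
  list(solute = solute_properties(
         "synthetic solute", 2.3e-4,
         crit = critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25, omega = 0.5)),
       psub = sublimation_model(20, 70000),
       k12 = 0.1)
}

classical_dataset <- function(tr, noise_cv = 0) {
  cfg <- generator_config(
    temperatures = c(313.15, 333.15),
    pressures_bar = c(120, 180, 240, 300),
    truth = list(route = "classical", solute = tr$solute, psub = tr$psub,
                 eos = eos_form("pr"), rule = "van_der_waals",
                 k12 = tr$k12),
    noise_cv = noise_cv, seed = 2)
  generate_dataset(cfg)
}

test_that("fit_schmitt_reid recovers generating (a2, b2) on noiseless data", {
  ds <- generate_dataset(penicillin_fixture("penG"))
  tr <- attr(ds, "truth")
  fit <- fit_schmitt_reid(ds, tr$solute, tr$psub, n_starts = 3, seed = 1)
  expect_lt(abs(fit$params$a2 / tr$solute$sr$a2 - 1), 0.01)
  expect_lt(abs(fit$params$b2 / tr$solute$sr$b2 - 1), 0.01)
  expect_lt(fit$aard_global, 0.5)
  expect_true(fit$converged)
})

test_that("reported AARD equals an independent forward re-evaluation", {
  ds <- generate_dataset(penicillin_fixture("penG", noise_cv = 0.08,
                                            seed = 3))
  tr <- attr(ds, "truth")
  fit <- fit_schmitt_reid(ds, tr$solute, tr$psub, n_starts = 2, seed = 1)
  # independent route: the scalar solubility() path, not the fitter's
  # vectorized objective
  sol_hat <- solute_properties(
    "refit", tr$solute$v2s,
    sr = schmitt_reid_params(fit$params$a2, fit$params$b2))
  y_re <- solubility(ds$temperature_K, ds$pressure_bar * 1e5, sol_hat,
                     clausius_pressure(tr$psub, ds$temperature_K))
  expect_equal(fit$aard_global, aard(ds$y2, y_re), tolerance = 1e-8)
})

test_that("fits are deterministic given the seed", {
  ds <- generate_dataset(penicillin_fixture("penV", noise_cv = 0.08,
                                            seed = 5))
  tr <- attr(ds, "truth")
  f1 <- fit_schmitt_reid(ds, tr$solute, tr$psub, n_starts = 3, seed = 42)
  f2 <- fit_schmitt_reid(ds, tr$solute, tr$psub, n_starts = 3, seed = 42)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$aard_global, f2$aard_global)
})

test_that("a wrong sublimation pressure at one isotherm wrecks the fit", {
  # a 10x error in one isotherm's p_sub cannot be absorbed by the
  # temperature-independent (a2, b2): the global AARD blows up and the
  # per-isotherm AARDs become strongly heterogeneous
  ds <- generate_dataset(penicillin_fixture("penG"))
  tr <- attr(ds, "truth")
  temps <- sort(unique(ds$temperature_K))
  ps <- clausius_pressure(tr$psub, temps)
  ps[1] <- ps[1] * 10 # corrupt the lowest isotherm
  fit <- fit_schmitt_reid(ds, tr$solute, setNames(ps, temps),
                          n_starts = 3, seed = 1)
  clean <- fit_schmitt_reid(ds, tr$solute, tr$psub, n_starts = 3, seed = 1)
  expect_gt(fit$aard_global, 100 * clean$aard_global)
  expect_gt(fit$aard_global, 10)
  expect_gt(max(fit$aard_by_T), 3 * min(fit$aard_by_T))
})

test_that("fit_classical recovers k12 when sublimation pressures are fixed", {
  tr <- classical_truth()
  ds <- classical_dataset(tr)
  fit <- fit_classical(ds, tr$solute, eos = "pr", rule = "van_der_waals",
                       psub_mode = "fixed", psub = tr$psub,
                       n_starts = 2, seed = 1)
  expect_lt(abs(fit$params$k12 - tr$k12), 1e-3)
  expect_lt(fit$aard_global, 0.5)
})

test_that("fit_classical recovers k12 and per-isotherm psub jointly", {
  tr <- classical_truth()
  ds <- classical_dataset(tr)
  fit <- fit_classical(ds, tr$solute, eos = "pr", rule = "van_der_waals",
                       psub_mode = "per_isotherm_free",
                       n_starts = 2, seed = 1)
  temps <- sort(unique(ds$temperature_K))
  ps_true <- clausius_pressure(tr$psub, temps)
  expect_lt(fit$aard_global, 0.5)
  expect_true(all(abs(fit$params$psub / ps_true - 1) < 0.05))
})

test_that("under-determined classical fits are rejected", {
  tr <- classical_truth()
  ds <- classical_dataset(tr)
  expect_error(
    fit_classical(ds[1, ], tr$solute, psub_mode = "per_isotherm_free"),
    "under-determined")
  expect_error(
    fit_classical(ds, tr$solute, psub_mode = "fixed"),
    "psub")
})
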
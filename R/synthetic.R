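#' Configuration for the synthetic solubility-data generator
#'
#' Describes a forward-simulated isothermal solubility study: the (T, P)
#' grid, the generating truth (route, solute, sublimation pressures and
#' route parameters), multiplicative lognormal measurement noise, and
#' optional constructed outliers.
#'
#' @param temperatures Isotherm temperatures, K.
#' @param pressures_bar Pressure grid per isotherm, bar.
#' @param truth List with `route` ("schmitt_reid" or "classical"),
#'   `solute` ([solute_properties()]), `psub` ([sublimation_model()] or
#'   per-isotherm pressures, Pa), and for the classical route `eos`,
#'   `rule`, `k12`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise (0 = noiseless). Default 0.08, typical scatter of
#'   static-method solubility measurements.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @param outliers Optional list of `c(T, P_bar, multiplier)` triples
#'   applied after the noise.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(temperatures, pressures_bar, truth,
                             noise_cv = 0.08, seed = 1, outliers = NULL) {
  stopifnot(is.numeric(temperatures), is.numeric(pressures_bar),
            all(temperatures > 0), all(pressures_bar > 0))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  stopifnot(is.list(truth), !is.null(truth$route), !is.null(truth$solute),
            !is.null(truth$psub))
  structure(list(temperatures = temperatures, pressures_bar = pressures_bar,
                 truth = truth, noise_cv = noise_cv, seed = seed,
                 outliers = outliers),
            class = "generator_config")
}

#' Generate a synthetic solubility dataset with known truth
#'
#' Runs the forward compressed-gas model over the configured grid, applies
#' strictly positive multiplicative lognormal noise with the configured CV
#' (mean-one, so no systematic bias), then any constructed outlier
#' multipliers. The generating truth is attached as `attr(, "truth")` for
#' recovery tests.
#'
#' @param config A [generator_config()].
#' @return A `solubility_dataset` data frame (`temperature_K`,
#'   `pressure_bar`, `y2`) with the truth attached.
#' @examples
#' ds <- generate_dataset(penicillin_fixture("penG"))
#' nrow(ds) # 18
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tr <- config$truth
  grid <- expand.grid(pressure_bar = config$pressures_bar,
                      temperature_K = config$temperatures)[, 2:1]
  temps <- sort(unique(grid$temperature_K))
  ps_iso <- .psub_by_isotherm(tr$psub, temps)
  y2 <- vapply(seq_len(nrow(grid)), function(i) {
    Ti <- grid$temperature_K[i]
    Pi <- grid$pressure_bar[i] * 1e5
    tryCatch(
      if (tr$route == "schmitt_reid") {
        solubility(Ti, Pi, tr$solute, ps_iso[as.character(Ti)],
                   route = "schmitt_reid")
      } else {
        solubility(Ti, Pi, tr$solute, ps_iso[as.character(Ti)],
                   route = "classical",
                   eos = if (is.null(tr$eos)) eos_form("pr") else tr$eos,
                   rule = if (is.null(tr$rule)) "van_der_waals" else tr$rule,
                   k12 = if (is.null(tr$k12)) 0 else tr$k12)
      },
      error = function(e)
        stop(sprintf("forward model failed at T = %g K, P = %g bar: %s",
                     Ti, Pi / 1e5, conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  if (config$noise_cv > 0) {
    set.seed(config$seed)
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    y2 <- y2 * exp(rnorm(length(y2), -sdlog^2 / 2, sdlog))
  }
  if (!is.null(config$outliers)) {
    for (o in config$outliers) {
      i <- which(abs(grid$temperature_K - o[1]) < 1e-9 &
                 abs(grid$pressure_bar - o[2]) < 1e-9)
      if (length(i) != 1)
        stop(sprintf("outlier point (%g K, %g bar) not on the grid",
                     o[1], o[2]), call. = FALSE)
      y2[i] <- y2[i] * o[3]
    }
  }
  ds <- solubility_dataset(data.frame(grid, y2 = y2))
  attr(ds, "truth") <- tr
  ds
}

#' Penicillin-like generator configurations
#'
#' Ready-made synthetic study designs emulating the two penicillin
#' solubility studies: `"penG"` gives 3 isotherms at 313.15/323.15/333.15 K
#' with 6 pressures each (N = 18), `"penV"` 3 isotherms at
#' 314.85/324.85/334.85 K with 8 pressures each (N = 24), both spanning
#' 100-350 bar. The generating truth is the Schmitt-Reid forward model
#' with the Clausius-Clapeyron sublimation models
#' (AS = 26.2, dHs = 85.3 kJ/mol) and (AS = 12.8, dHs = 41.9 kJ/mol), the
#' experimental solid molar volumes (226.1 and 243.2 cm^3/mol), covolumes
#' b2 at the published regressed magnitudes (1.98e-4 / 2.93e-4 m^3/mol),
#' and SI attraction parameters a2 chosen so the noiseless solubilities
#' span the reported 1e-6 to 1e-4 mole-fraction window.
#'
#' @param which `"penG"` or `"penV"`.
#' @param noise_cv Noise level (default 0: noiseless truth).
#' @param seed RNG seed for the noise.
#' @param outliers `TRUE` to perturb the lowest-pressure point of each of
#'   the two upper isotherms by a factor of five (one above, one below the
#'   MST consistency line, emulating the two off-line points removed in
#'   such studies), or an explicit list as in [generator_config()].
#' @return A [generator_config()].
#' @examples
#' nrow(generate_dataset(penicillin_fixture("penV"))) # 24
#' @export
penicillin_fixture <- function(which = c("penG", "penV"), noise_cv = 0,
                               seed = 1, outliers = FALSE) {
  which <- match.arg(which)
  if (which == "penG") {
    temps <- c(313.15, 323.15, 333.15)
    press <- c(100, 150, 200, 250, 300, 350)
    solute <- solute_properties("penicillin G (synthetic fixture)",
                                v2s = 2.261e-4,
                                sr = schmitt_reid_params(12.8, 1.98e-4))
    psub <- sublimation_model(26.2, 85300)
    out <- list(c(323.15, 100, 5), c(333.15, 100, 0.2))
  } else {
    temps <- c(314.85, 324.85, 334.85)
    press <- seq(100, 345, by = 35)
    solute <- solute_properties("penicillin V (synthetic fixture)",
                                v2s = 2.432e-4,
                                sr = schmitt_reid_params(16, 2.93e-4))
    psub <- sublimation_model(12.8, 41900)
    out <- list(c(324.85, 100, 5), c(334.85, 100, 0.2))
  }
  if (isFALSE(outliers)) out <- NULL
  else if (!isTRUE(outliers)) out <- outliers
  generator_config(temperatures = temps, pressures_bar = press,
                   truth = list(route = "schmitt_reid", solute = solute,
                                psub = psub),
                   noise_cv = noise_cv, seed = seed, outliers = out)
}
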
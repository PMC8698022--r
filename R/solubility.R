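#' Solute property bundle
#'
#' Groups the solid-state and EoS inputs of one solute: solid molar volume,
#' optional (pseudo-)critical set for the classical route, and optional
#' Schmitt-Reid (a2, b2) for the infinite-dilution route.
#'
#' @param name Compound name.
#' @param v2s Solid molar volume, m^3/mol.
#' @param crit Optional [critical_set()].
#' @param sr Optional [schmitt_reid_params()].
#' @return An object of class `solute_properties`.
#' @examples
#' solute_properties("penicillin G", v2s = 2.261e-4,
#'                   sr = schmitt_reid_params(12.8, 1.98e-4))
#' @export
solute_properties <- function(name, v2s, crit = NULL, sr = NULL) {
  if (v2s <= 0) stop("v2s must be positive", call. = FALSE)
  if (!is.null(crit)) stopifnot(inherits(crit, "critical_set"))
  if (!is.null(sr)) stopifnot(inherits(sr, "schmitt_reid_params"))
  structure(list(name = name, v2s = v2s, crit = crit, sr = sr),
            class = "solute_properties")
}

#' Poynting pressure correction of the solid-phase fugacity
#'
#' Full form exp\[v2s (P - p_sub) / RT\]; the simplified convention used in
#' regression work (where P >> p_sub) drops p_sub: exp\[v2s P / RT\].
#'
#' @param v2s Solid molar volume, m^3/mol.
#' @param T Temperature, K.
#' @param P Pressure, Pa.
#' @param p_sub Sublimation pressure, Pa (ignored unless `full`).
#' @param full Use the full (P - p_sub) driving pressure.
#' @return Dimensionless factor.
#' @examples
#' poynting_factor(2.261e-4, 313.15, 15e6) # about 3.68
#' @export
poynting_factor <- function(v2s, T, P, p_sub = 0, full = FALSE) {
  if (any(P <= 0) || any(p_sub < 0)) stop("need P > 0, p_sub >= 0",
                                          call. = FALSE)
  dP <- if (full) P - p_sub else P
  exp(v2s * dP / (.R_GAS * T))
}

#' Equilibrium solid solubility from the compressed-gas model
#'
#' Solves y2 = (p_sub / P) * Poynting / phi2 for the solute mole fraction
#' in the supercritical phase. On the Schmitt-Reid route phi2 is independent
#' of composition and the expression is evaluated directly; on the classical
#' route phi2 depends on y2 through the mixture parameters and the equation
#' is solved by fixed-point iteration seeded at the phi2 = 1 value.
#'
#' @param T Temperature, K (vectorized with `P`).
#' @param P Pressure, Pa.
#' @param solute A [solute_properties()]; needs `sr` for the Schmitt-Reid
#'   route, `crit` for the classical route.
#' @param p_sub Sublimation pressure at T, Pa (scalar or vector along T).
#' @param route `"schmitt_reid"` or `"classical"`.
#' @param eos EoS for the classical route (ignored for Schmitt-Reid, which
#'   is PR by construction).
#' @param rule Combining rule for the classical route.
#' @param k12 Binary interaction parameter (classical route).
#' @param poynting `"simplified"` (default regression convention) or
#'   `"full"`.
#' @param co2 CO2 critical set.
#' @param tol,max_iter Fixed-point controls (classical route).
#' @return Solute mole fraction y2.
#' @examples
#' pen_g <- solute_properties("penicillin G", 2.261e-4,
#'                            sr = schmitt_reid_params(12.8, 1.98e-4))
#' solubility(313.15, 20e6, pen_g, p_sub = 1.41e-3)
#' @export
solubility <- function(T, P, solute, p_sub,
                       route = c("schmitt_reid", "classical"),
                       eos = eos_form("pr"),
                       rule = c("van_der_waals", "lorentz_berthelot"),
                       k12 = 0,
                       poynting = c("simplified", "full"),
                       co2 = co2_critical(),
                       tol = 1e-10, max_iter = 200) {
  route <- match.arg(route)
  rule <- match.arg(rule)
  poynting <- match.arg(poynting)
  eos <- .as_eos(eos)
  stopifnot(inherits(solute, "solute_properties"))
  n <- max(length(T), length(P))
  T <- rep_len(T, n)
  P <- rep_len(P, n)
  p_sub <- rep_len(p_sub, n)
  if (any(p_sub <= 0)) stop("p_sub must be positive", call. = FALSE)
  full <- poynting == "full"
  vapply(seq_len(n), function(i) {
    poy <- poynting_factor(solute$v2s, T[i], P[i], p_sub[i], full = full)
    base <- p_sub[i] / P[i] * poy
    if (route == "schmitt_reid") {
      if (is.null(solute$sr))
        stop("Schmitt-Reid route needs solute$sr", call. = FALSE)
      p1 <- pure_params(eos_form("pr"), co2, T[i])
      y2 <- base / phi2_schmitt_reid(T[i], P[i], p1, solute$sr)
    } else {
      if (is.null(solute$crit))
        stop("classical route needs solute$crit", call. = FALSE)
      y2 <- base # phi2 = 1 seed
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        phi <- phi2_classical(eos, T[i], P[i], min(y2, 1 - 1e-12),
                              co2, solute$crit, k12, rule)
        y2_new <- base / phi
        if (abs(y2_new - y2) <= tol * max(abs(y2_new), 1e-300)) {
          y2 <- y2_new
          ok <- TRUE
          break
        }
        y2 <- y2_new
        if (!is.finite(y2) || y2 >= 1)
          stop(sprintf("solubility iteration diverged at T = %g, P = %g (last y2 = %g)",
                       T[i], P[i], y2), call. = FALSE)
      }
      if (!ok) stop("solubility fixed point did not converge", call. = FALSE)
    }
    if (!is.finite(y2) || y2 <= 0 || y2 >= 1)
      stop(sprintf("computed y2 = %g outside (0, 1) at T = %g, P = %g",
                   y2, T[i], P[i]), call. = FALSE)
    y2
  }, numeric(1))
}
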
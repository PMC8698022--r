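#' Lorentz-Berthelot cross critical constants and RK cross attraction
#'
#' Combines two critical sets into the cross (i, j) pseudo-criticals:
#' TCij = (1 - k12) sqrt(Tci Tcj), VCij = ((Vci^(1/3) + Vcj^(1/3))/2)^3,
#' ZCij = (Zci + Zcj)/2, PCij = ZCij R TCij / VCij, and the Redlich-Kwong
#' dimensional cross attraction aij = 0.42748 R^2 TCij^2.5 / PCij
#' (Pa m^6 K^0.5 mol^-2; divide by sqrt(T) for the effective a at T).
#'
#' @param crit1,crit2 [critical_set()] objects with `Vc` and `Zc` present.
#' @param k12 Binary interaction parameter, |k12| <= 1.
#' @return List with `Tc`, `Pc`, `Vc`, `Zc`, `omega` (arithmetic mean) and
#'   `aij`.
#' @examples
#' cross_params_lb(co2_critical(),
#'                 critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25), k12 = 0.1)
#' @export
cross_params_lb <- function(crit1, crit2, k12 = 0) {
  stopifnot(inherits(crit1, "critical_set"), inherits(crit2, "critical_set"))
  if (abs(k12) > 1) stop("|k12| must not exceed 1", call. = FALSE)
  if (is.null(crit1$Vc) || is.null(crit2$Vc) ||
      is.null(crit1$Zc) || is.null(crit2$Zc))
    stop("Lorentz-Berthelot combining needs Vc and Zc for both compounds",
         call. = FALSE)
  Tcij <- (1 - k12) * sqrt(crit1$Tc * crit2$Tc)
  Vcij <- ((crit1$Vc^(1 / 3) + crit2$Vc^(1 / 3)) / 2)^3
  Zcij <- (crit1$Zc + crit2$Zc) / 2
  Pcij <- Zcij * .R_GAS * Tcij / Vcij
  aij <- if (Tcij > 0) 0.42748 * .R_GAS^2 * Tcij^2.5 / Pcij else 0
  list(Tc = Tcij, Pc = Pcij, Vc = Vcij, Zc = Zcij,
       omega = (crit1$omega + crit2$omega) / 2, aij = aij)
}

#' Quadratic van der Waals mixing of binary EoS parameters
#'
#' a_mix = (1-y2)^2 a11 + 2 y2 (1-y2) a12 + y2^2 a22;
#' b_mix = (1-y2) b1 + y2 b2.
#'
#' @param y2 Solute mole fraction in `[0, 1]`.
#' @param a11,a12,a22 Attraction parameters, Pa m^6 mol^-2.
#' @param b1,b2 Covolumes, m^3/mol.
#' @return List with `a` and `b`.
#' @export
mix_vdw <- function(y2, a11, a12, a22, b1, b2) {
  if (y2 < 0 || y2 > 1) stop("y2 must lie in [0, 1]", call. = FALSE)
  y1 <- 1 - y2
  list(a = y1^2 * a11 + 2 * y1 * y2 * a12 + y2^2 * a22,
       b = y1 * b1 + y2 * b2)
}

# Cross attraction a12(T) for the chosen rule.
# van der Waals: a12 = (1 - k12) sqrt(a1 a2) from each compound's own a(T).
# Lorentz-Berthelot: the chosen EoS's own a(T) evaluated on the cross
# pseudo-criticals (with omega_ij the arithmetic mean); for RK this reduces
# exactly to aij/sqrt(T) with aij from cross_params_lb().
.cross_a <- function(eos, crit1, crit2, k12, T,
                     rule = c("van_der_waals", "lorentz_berthelot")) {
  rule <- match.arg(rule)
  if (rule == "van_der_waals") {
    a1 <- pure_params(eos, crit1, T)$a
    a2 <- pure_params(eos, crit2, T)$a
    (1 - k12) * sqrt(a1 * a2)
  } else {
    cc <- cross_params_lb(crit1, crit2, k12)
    if (cc$Tc <= 0) return(0)
    crit12 <- critical_set(Tc = cc$Tc, Pc = cc$Pc, Vc = cc$Vc,
                           omega = cc$omega)
    pure_params(eos, crit12, T)$a
  }
}

# Generic closed-form ln(phi_k) for component k of a binary mixture in a
# two-parameter cubic EoS with quadratic mixing:
#   ln phi_k = (b_k/b)(Z - 1) - ln(Z - B)
#              + (2 sum_j y_j a_kj - a b_k/b) / (b R T (sig - eps))
#                * ln((Z + eps B)/(Z + sig B))
.ln_phi_k <- function(eos, T, P, v, a_mix, b_mix, sum_ya_kj, b_k) {
  Z <- P * v / (.R_GAS * T)
  B <- b_mix * P / (.R_GAS * T)
  if (b_mix <= 0) {
    # a = b = 0 degenerates to an ideal gas (Z = 1, phi = 1)
    if (a_mix <= 0) return(0)
    stop("b_mix must be positive when a_mix > 0", call. = FALSE)
  }
  if (Z - B <= 0) stop("fluid root violates Z > B", call. = FALSE)
  att <- (2 * sum_ya_kj - a_mix * b_k / b_mix) /
    (b_mix * .R_GAS * T * (eos$sig - eos$eps)) *
    log((Z + eos$eps * B) / (Z + eos$sig * B))
  (b_k / b_mix) * (Z - 1) - log(Z - B) + att
}

#' Solute fugacity coefficient in a binary supercritical mixture
#'
#' Closed-form fugacity coefficient of the solute (component 2) in
#' CO2 (component 1) at composition y2, from the chosen cubic EoS with
#' quadratic van der Waals mixing of (a, b). The cross attraction a12
#' follows the selected combining rule: plain van der Waals
#' (a12 = (1-k12) sqrt(a11 a22)) or Lorentz-Berthelot combination of the
#' critical constants. Evaluated at the mixture's fluid-branch root.
#'
#' @param eos An [eos_form()] or its name.
#' @param T Temperature, K.
#' @param P Pressure, Pa.
#' @param y2 Solute mole fraction.
#' @param crit1 Solvent critical set (CO2: [co2_critical()]).
#' @param crit2 Solute (pseudo-)critical set.
#' @param k12 Binary interaction parameter.
#' @param rule Combining rule for a12.
#' @return Fugacity coefficient phi2 (dimensionless, > 0).
#' @examples
#' sol <- critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25, omega = 0.5)
#' phi2_classical("pr", 313.15, 20e6, 1e-5, co2_critical(), sol, k12 = 0.1)
#' @export
phi2_classical <- function(eos, T, P, y2, crit1, crit2, k12 = 0,
                           rule = c("van_der_waals", "lorentz_berthelot")) {
  eos <- .as_eos(eos)
  rule <- match.arg(rule)
  p1 <- pure_params(eos, crit1, T)
  p2 <- pure_params(eos, crit2, T)
  a12 <- .cross_a(eos, crit1, crit2, k12, T, rule)
  mx <- mix_vdw(y2, p1$a, a12, p2$a, p1$b, p2$b)
  fr <- .fluid_root(eos, mx, T, P)
  sum_ya <- (1 - y2) * a12 + y2 * p2$a
  exp(.ln_phi_k(eos, T, P, fr$v, mx$a, mx$b, sum_ya, p2$b))
}

#' Pure-fluid fugacity coefficient
#'
#' @inheritParams phi2_classical
#' @param crit Critical set of the fluid.
#' @return Fugacity coefficient (dimensionless).
#' @export
phi_pure <- function(eos, T, P, crit) {
  eos <- .as_eos(eos)
  pp <- pure_params(eos, crit, T)
  fr <- .fluid_root(eos, pp, T, P)
  exp(.ln_phi_k(eos, T, P, fr$v, pp$a, pp$b, pp$a, pp$b))
}

#' Schmitt-Reid solute parameters
#'
#' Temperature-independent solute attraction and covolume for the
#' infinite-dilution modified Peng-Robinson route, treated as adjustable
#' parameters so that solute critical-property estimation is avoided.
#'
#' @param a2 Solute attraction parameter, Pa m^6 mol^-2.
#' @param b2 Solute covolume, m^3/mol.
#' @return An object of class `schmitt_reid_params`.
#' @export
schmitt_reid_params <- function(a2, b2) {
  if (a2 <= 0 || b2 <= 0) stop("a2 and b2 must be positive", call. = FALSE)
  structure(list(a2 = a2, b2 = b2), class = "schmitt_reid_params")
}

#' Infinite-dilution solute fugacity coefficient (Schmitt-Reid modified PR)
#'
#' The Schmitt-Reid simplification of Peng-Robinson drops all terms of
#' order y2 and the binary interaction parameter (a12 = sqrt(a1 a2)),
#' so phi2 is evaluated at the pure-CO2 fluid root (V, Z):
#' \deqn{\ln\varphi_2 = \frac{b_2}{b_1}(Z-1) - \ln\frac{P(V-b_1)}{RT}
#'  - \frac{a_1}{\sqrt8 RT b_1}\left(2\sqrt{a_2/a_1} - \frac{b_2}{b_1}\right)
#'    \ln\frac{V+(1+\sqrt2)b_1}{V+(1-\sqrt2)b_1}}
#' which is exactly the y2 -> 0 limit of the classical PR expression with
#' k12 = 0.
#'
#' @param T Temperature, K.
#' @param P Pressure, Pa.
#' @param pure1 Pure-CO2 PR parameters at T, from
#'   `pure_params("pr", co2_critical(), T)`.
#' @param sr [schmitt_reid_params()].
#' @return Fugacity coefficient phi2 (dimensionless).
#' @examples
#' p1 <- pure_params("pr", co2_critical(), 313.15)
#' phi2_schmitt_reid(313.15, 20e6, p1, schmitt_reid_params(12.8, 1.98e-4))
#' @export
phi2_schmitt_reid <- function(T, P, pure1, sr) {
  stopifnot(inherits(sr, "schmitt_reid_params"))
  a1 <- pure1$a
  b1 <- pure1$b
  fr <- .fluid_root(eos_form("pr"), pure1, T, P)
  v <- fr$v
  if (v + (1 - sqrt(2)) * b1 <= 0)
    stop("volume root too small: V <= (sqrt(2)-1) b1", call. = FALSE)
  lnphi <- (sr$b2 / b1) * (fr$Z - 1) -
    log(P * (v - b1) / (.R_GAS * T)) -
    a1 / (sqrt(8) * .R_GAS * T * b1) *
      (2 * sqrt(sr$a2 / a1) - sr$b2 / b1) *
      log((v + (1 + sqrt(2)) * b1) / (v + (1 - sqrt(2)) * b1))
  exp(lnphi)
}
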
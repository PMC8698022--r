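# Physical constants (SI). Internal units are Pa, K, m^3/mol throughout;
# bar appears only at I/O boundaries (CSV columns, printed tables).
.R_GAS <- 8.314462618 # J mol^-1 K^-1
.M_CO2 <- 44.01e-3    # kg mol^-1

#' Critical constants and acentric factor of a compound
#'
#' Container for the (pseudo-)critical set used by the cubic equations of
#' state and the Lorentz-Berthelot combining rules. Any one of `Pc`, `Zc`
#' may be omitted and is completed from `Zc = Pc*Vc/(R*Tc)`.
#'
#' @param Tc Critical temperature, K.
#' @param Pc Critical pressure, Pa (optional if `Vc` and `Zc` given).
#' @param Vc Critical molar volume, m^3/mol (optional unless needed).
#' @param Zc Critical compressibility factor (optional if `Pc` and `Vc` given).
#' @param omega Acentric factor (dimensionless).
#' @return An object of class `critical_set`.
#' @examples
#' co2_critical()
#' critical_set(Tc = 700, Vc = 6e-4, Zc = 0.25, omega = 0.5)
#' @export
critical_set <- function(Tc, Pc = NULL, Vc = NULL, Zc = NULL, omega = 0) {
  if (!is.numeric(Tc) || Tc <= 0) stop("Tc must be positive", call. = FALSE)
  if (is.null(Pc) && (is.null(Vc) || is.null(Zc)))
    stop("supply Pc, or both Vc and Zc", call. = FALSE)
  if (is.null(Pc)) Pc <- Zc * .R_GAS * Tc / Vc
  if (is.null(Zc) && !is.null(Vc)) Zc <- Pc * Vc / (.R_GAS * Tc)
  if (Pc <= 0) stop("Pc must be positive", call. = FALSE)
  if (!is.null(Vc) && Vc <= 0) stop("Vc must be positive", call. = FALSE)
  if (!is.null(Zc) && (Zc <= 0 || Zc >= 1))
    stop("Zc must lie in (0, 1)", call. = FALSE)
  structure(list(Tc = Tc, Pc = Pc, Vc = Vc, Zc = Zc, omega = omega),
            class = "critical_set")
}

#' Carbon dioxide critical constants
#'
#' Standard literature values: Tc = 304.13 K, Pc = 7.3773 MPa,
#' Vc = 9.412e-5 m^3/mol, acentric factor 0.2239. All overridable.
#'
#' @inheritParams critical_set
#' @return A [critical_set()].
#' @export
co2_critical <- function(Tc = 304.13, Pc = 7.3773e6, Vc = 9.412e-5,
                         omega = 0.2239) {
  critical_set(Tc = Tc, Pc = Pc, Vc = Vc, omega = omega)
}
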
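#' Clausius-Clapeyron sublimation-pressure model
#'
#' ln p_sub(Pa) = AS - BS / (R T), with BS the sublimation enthalpy
#' (J/mol) and AS the dimensionless intercept in ln(Pa).
#'
#' @param AS Intercept, ln(Pa).
#' @param BS Sublimation enthalpy, J/mol (> 0 for physical solids).
#' @return An object of class `sublimation_model`.
#' @examples
#' sublimation_model(26.2, 85300) # penicillin G
#' @export
sublimation_model <- function(AS, BS) {
  if (!is.finite(AS) || !is.finite(BS))
    stop("AS and BS must be finite", call. = FALSE)
  structure(list(AS = AS, BS = BS), class = "sublimation_model")
}

#' @export
print.sublimation_model <- function(x, ...) {
  cat(sprintf("<sublimation_model> ln P2sub(Pa) = %.4g - %.4g/(R T)  [dHs = %.1f kJ/mol]\n",
              x$AS, x$BS, x$BS / 1000))
  invisible(x)
}

#' Sublimation pressure at temperature T
#'
#' @param model A [sublimation_model()].
#' @param T Temperature, K (vectorized).
#' @return Sublimation pressure, Pa.
#' @examples
#' clausius_pressure(sublimation_model(26.2, 85300), 313.15) # 1.41e-3 Pa
#' @export
clausius_pressure <- function(model, T) {
  stopifnot(inherits(model, "sublimation_model"))
  if (any(T <= 0)) stop("T must be positive", call. = FALSE)
  exp(model$AS - model$BS / (.R_GAS * T))
}

#' Fit a Clausius-Clapeyron model to (T, p_sub) pairs
#'
#' Ordinary least squares of ln p_sub against 1/T; the slope s gives
#' BS = -s R and the intercept AS. The fitted BS is invariant to the
#' pressure unit (a unit change only shifts AS).
#'
#' @param T Temperatures, K (>= 2 distinct values).
#' @param p_sub Sublimation pressures, Pa (> 0).
#' @return A [sublimation_model()].
#' @examples
#' m <- sublimation_model(10, 50000)
#' fit_clausius(c(310, 330), clausius_pressure(m, c(310, 330)))
#' @export
fit_clausius <- function(T, p_sub) {
  if (length(T) != length(p_sub) || length(T) < 2)
    stop("need >= 2 (T, p_sub) pairs", call. = FALSE)
  if (anyDuplicated(T)) stop("temperatures must be distinct", call. = FALSE)
  if (any(p_sub <= 0)) stop("p_sub must be positive", call. = FALSE)
  fit <- lm(log(p_sub) ~ I(1 / T))
  co <- coef(fit)
  sublimation_model(AS = unname(co[1]), BS = -unname(co[2]) * .R_GAS)
}

#' Relative discrepancy between two sublimation pressures
#'
#' 100 |p_a - p_b| / p_a, with p_a the reference (first-named) pressure.
#' Scale-invariant: any common unit cancels.
#'
#' @param p_a Reference pressure (> 0), any common unit.
#' @param p_b Compared pressure.
#' @return Discrepancy, percent.
#' @examples
#' pressure_discrepancy(2.82e-12, 3.55e-12) # about 26
#' @export
pressure_discrepancy <- function(p_a, p_b) {
  if (any(p_a <= 0)) stop("reference pressure p_a must be positive",
                          call. = FALSE)
  100 * abs(p_a - p_b) / p_a
}
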
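#' Cubic equation-of-state form
#'
#' Defines one of the three two-parameter cubic equations of state in the
#' generic pressure-explicit form
#' \deqn{P = \frac{RT}{v-b} - \frac{a(T)}{(v+\epsilon b)(v+\sigma b)}}
#' with (\eqn{\epsilon}, \eqn{\sigma}) = (0, 1) for Redlich-Kwong and
#' Soave-Redlich-Kwong and (1-\eqn{\sqrt2}, 1+\eqn{\sqrt2}) for
#' Peng-Robinson, and the matching temperature function:
#' RK uses \eqn{\alpha = 1/\sqrt{T_r}} folded into a(T), SRK the Soave form
#' with s = 0.48 + 1.574\eqn{\omega} - 0.176\eqn{\omega^2}, PR the Soave-type
#' form with \eqn{\kappa} = 0.37464 + 1.54226\eqn{\omega} -
#' 0.26992\eqn{\omega^2}, both applied to (1 - \eqn{\sqrt{T_r}}).
#'
#' @param name One of `"rk"`, `"srk"`, `"pr"` (case-insensitive).
#' @return An object of class `eos_form` with elements `name`, `omega_a`,
#'   `omega_b`, `eps`, `sig`, `alpha_kind`.
#' @examples
#' eos_form("pr")
#' @export
eos_form <- function(name = c("pr", "srk", "rk")) {
  name <- tolower(name)
  name <- match.arg(name)
  out <- switch(name,
    rk  = list(name = "rk",  omega_a = 0.42748, omega_b = 0.08664,
               eps = 0, sig = 1, alpha_kind = "inverse_sqrt_T"),
    srk = list(name = "srk", omega_a = 0.42748, omega_b = 0.08664,
               eps = 0, sig = 1, alpha_kind = "soave"),
    pr  = list(name = "pr",  omega_a = 0.45724, omega_b = 0.07780,
               eps = 1 - sqrt(2), sig = 1 + sqrt(2), alpha_kind = "pr")
  )
  structure(out, class = "eos_form")
}

.as_eos <- function(eos) {
  if (inherits(eos, "eos_form")) eos else eos_form(eos)
}

.alpha <- function(eos, Tr, omega) {
  switch(eos$alpha_kind,
    inverse_sqrt_T = 1 / sqrt(Tr),
    soave = {
      s <- 0.48 + 1.574 * omega - 0.176 * omega^2
      (1 + s * (1 - sqrt(Tr)))^2
    },
    pr = {
      k <- 0.37464 + 1.54226 * omega - 0.26992 * omega^2
      (1 + k * (1 - sqrt(Tr)))^2
    }
  )
}

#' Pure-component cubic-EoS parameters
#'
#' Evaluates the attraction parameter a(T) (Pa m^6 mol^-2, with the
#' temperature function folded in) and the covolume b (m^3/mol) from a
#' critical set:
#' a(T) = \eqn{\Omega_a R^2 T_c^2 / P_c \cdot \alpha(T_r, \omega)},
#' b = \eqn{\Omega_b R T_c / P_c}.
#'
#' @param eos An [eos_form()] (or its name).
#' @param crit A [critical_set()].
#' @param T Temperature, K.
#' @return An object of class `pure_params` with elements `a`, `b`, `T`.
#' @examples
#' pure_params(eos_form("pr"), co2_critical(), 313.15)
#' @export
pure_params <- function(eos, crit, T) {
  eos <- .as_eos(eos)
  stopifnot(inherits(crit, "critical_set"))
  if (!is.numeric(T) || any(T <= 0)) stop("T must be positive", call. = FALSE)
  Tr <- T / crit$Tc
  a <- eos$omega_a * .R_GAS^2 * crit$Tc^2 / crit$Pc *
    .alpha(eos, Tr, crit$omega)
  b <- eos$omega_b * .R_GAS * crit$Tc / crit$Pc
  structure(list(a = a, b = b, T = T), class = "pure_params")
}

# Real roots of z^3 + c2 z^2 + c1 z + c0 = 0, analytic (trigonometric /
# Cardano) followed by Newton polishing on the monic cubic.
.cubic_real <- function(c2, c1, c0) {
  p <- c1 - c2^2 / 3
  q <- 2 * c2^3 / 27 - c2 * c1 / 3 + c0
  disc <- (q / 2)^2 + (p / 3)^3
  roots <- if (disc > 0) {
    u <- -q / 2 + sqrt(disc)
    v <- -q / 2 - sqrt(disc)
    cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
    cbrt(u) + cbrt(v)
  } else if (abs(p) < 1e-300) {
    rep(0, 3)
  } else {
    m <- 2 * sqrt(-p / 3)
    arg <- 3 * q / (p * m)
    arg <- min(1, max(-1, arg))
    theta <- acos(arg) / 3
    m * cos(theta - 2 * pi * (0:2) / 3)
  }
  roots <- roots - c2 / 3
  # Newton polish; the analytic formulas lose accuracy for near-degenerate
  # discriminants.
  f <- function(z) ((z + c2) * z + c1) * z + c0
  fp <- function(z) (3 * z + 2 * c2) * z + c1
  for (i in 1:3) {
    d <- fp(roots)
    step <- ifelse(abs(d) > 0, f(roots) / d, 0)
    roots <- roots - step
  }
  sort(roots)
}

#' Solve the cubic EoS for molar volume
#'
#' Finds all real molar-volume roots v > b of the pressure form at (T, P).
#' The cubic is solved in compressibility-factor space
#' (better conditioned than v-space) and polished by Newton iteration.
#' The largest root is the vapor/supercritical branch used for the fluid
#' phase; middle roots are mechanically unstable.
#'
#' @param eos An [eos_form()] (or its name).
#' @param params A [pure_params()] or any list with elements `a`
#'   (Pa m^6 mol^-2) and `b` (m^3/mol), e.g. mixture parameters.
#' @param T Temperature, K.
#' @param P Pressure, Pa.
#' @return Numeric vector of real roots v > b, m^3/mol, sorted ascending.
#' @examples
#' solve_volume(eos_form("pr"), pure_params("pr", co2_critical(), 313.15),
#'              313.15, 15e6)
#' @export
solve_volume <- function(eos, params, T, P) {
  eos <- .as_eos(eos)
  if (T <= 0 || P <= 0) stop("T and P must be positive", call. = FALSE)
  a <- params$a
  b <- params$b
  A <- a * P / (.R_GAS * T)^2
  B <- b * P / (.R_GAS * T)
  u <- eos$eps + eos$sig
  w <- eos$eps * eos$sig
  # z^3 + c2 z^2 + c1 z + c0 = 0
  c2 <- -(1 + B - u * B)
  c1 <- A + w * B^2 - u * B - u * B^2
  c0 <- -(A * B + w * B^2 + w * B^3)
  z <- .cubic_real(c2, c1, c0)
  v <- z * .R_GAS * T / P
  v <- unique(v[v > b * (1 + 1e-12) & v > 0])
  if (length(v) == 0) {
    stop(sprintf(
      "no real volume root > b at T = %g K, P = %g Pa (a = %g, b = %g)",
      T, P, a, b), call. = FALSE)
  }
  sort(v)
}

# Fluid-branch (largest) root and its compressibility factor.
.fluid_root <- function(eos, params, T, P) {
  v <- max(solve_volume(eos, params, T, P))
  list(v = v, Z = P * v / (.R_GAS * T))
}

#' CO2 density from a cubic EoS
#'
#' Mass density of pure carbon dioxide at (T, P) from the fluid-branch
#' molar volume of the chosen equation of state (M = 44.01 g/mol).
#'
#' @param T Temperature, K (vectorized together with `P`).
#' @param P Pressure, Pa.
#' @param eos An [eos_form()] or its name; default Peng-Robinson.
#' @param crit CO2 critical set; default [co2_critical()].
#' @return Density, kg/m^3.
#' @examples
#' co2_density(313.15, 15e6)
#' @export
co2_density <- function(T, P, eos = eos_form("pr"), crit = co2_critical()) {
  eos <- .as_eos(eos)
  n <- max(length(T), length(P))
  T <- rep_len(T, n)
  P <- rep_len(P, n)
  vapply(seq_len(n), function(i) {
    pp <- pure_params(eos, crit, T[i])
    .M_CO2 / .fluid_root(eos, pp, T[i], P[i])$v
  }, numeric(1))
}

#' @export
print.eos_form <- function(x, ...) {
  cat(sprintf("<eos_form> %s (Omega_a = %.5f, Omega_b = %.5f, alpha = %s)\n",
              toupper(x$name), x$omega_a, x$omega_b, x$alpha_kind))
  invisible(x)
}
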
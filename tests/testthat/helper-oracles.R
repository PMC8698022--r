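# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: volumes come from the expanded polynomial via
# base::polyroot, fugacity coefficients from numerical quadrature of the
# defining volume integral.

R_GAS <- 8.314462618

# All real roots v > b of the cubic pressure form, via the expanded
# polynomial in v and polyroot():
#   P v^3 + [P(u-1)b - RT] v^2 + [P(w-u)b^2 - RT u b + a] v
#     + [-P w b^3 - RT w b^2 - a b] = 0
volume_roots_oracle <- function(eos, a, b, T, P) {
  u <- eos$eps + eos$sig
  w <- eos$eps * eos$sig
  RT <- R_GAS * T
  cf <- c(-P * w * b^3 - RT * w * b^2 - a * b,
          P * (w - u) * b^2 - RT * u * b + a,
          P * (u - 1) * b - RT,
          P)
  z <- polyroot(cf)
  v <- Re(z)[abs(Im(z)) < 1e-8 * pmax(1, Mod(z))]
  sort(unique(v[v > b * (1 + 1e-12) & v > 0]))
}

# ln(phi2) by quadrature of the defining integral
#   ln phi2 = 1/RT * int_V^Inf [ dP/dn2 - RT/V ] dV - ln Z
# with P(n1, n2, V_total) from the quadratic mixing rules and a central
# finite difference for dP/dn2 at constant (T, V_total, n1).
phi2_quadrature_oracle <- function(eos, T, P, y2, a11, a12, a22, b1, b2) {
  RT <- R_GAS * T
  p_total <- function(n1, n2, Vt) {
    n <- n1 + n2
    y <- n2 / n
    a <- (1 - y)^2 * a11 + 2 * y * (1 - y) * a12 + y^2 * a22
    b <- (1 - y) * b1 + y * b2
    n * RT / (Vt - n * b) -
      n^2 * a / ((Vt + eos$eps * n * b) * (Vt + eos$sig * n * b))
  }
  # mixture molar volume at the fluid root (n = 1 total moles)
  a_mix <- (1 - y2)^2 * a11 + 2 * y2 * (1 - y2) * a12 + y2^2 * a22
  b_mix <- (1 - y2) * b1 + y2 * b2
  v <- max(volume_roots_oracle(eos, a_mix, b_mix, T, P))
  Z <- P * v / RT
  # central difference; h large enough to beat the cancellation noise of
  # the O(1e7 Pa) pressure evaluations (P is polynomial in n2, so the
  # analytic continuation through small negative n2 is exact)
  h <- 1e-5
  integrand <- function(Vt) {
    vapply(Vt, function(V) {
      dPdn2 <- (p_total(1 - y2, y2 + h, V) - p_total(1 - y2, y2 - h, V)) /
        (2 * h)
      dPdn2 - RT / V
    }, numeric(1))
  }
  # piecewise finite integration (the finite-difference integrand is too
  # noisy for the Inf transform), closed by the 1/V^2 asymptotic tail:
  # f(V) ~ K/V^2 for large V, so the remainder beyond A is f(A) * A
  breaks <- v * c(1, 10, 1e3, 1e6)
  I <- 0
  for (k in seq_len(length(breaks) - 1)) {
    I <- I + integrate(integrand, breaks[k], breaks[k + 1],
                       rel.tol = 1e-8, abs.tol = 1e-5,
                       subdivisions = 1000L)$value
  }
  A <- breaks[length(breaks)]
  I <- I + integrand(A) * A
  I / RT - log(Z)
}

# Random thermodynamic state generators (supercritical CO2-like ranges).
random_solute_crit <- function() {
  critical_set(Tc = runif(1, 500, 900), Pc = runif(1, 1e6, 4e6),
               Vc = runif(1, 3e-4, 8e-4), omega = runif(1, 0, 1))
}

penG_truth <- function() {
  list(solute = solute_properties("penG fixture", 2.261e-4,
                                  sr = schmitt_reid_params(12.8, 1.98e-4)),
       psub = sublimation_model(26.2, 85300))
}
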
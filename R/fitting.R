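# Resolve per-isotherm sublimation pressures (Pa) for the sorted unique
# temperatures of a dataset: a sublimation_model, a named numeric
# (names = temperature), or an unnamed numeric in sorted-temperature order.
.psub_by_isotherm <- function(psub, temps) {
  if (inherits(psub, "sublimation_model"))
    return(setNames(clausius_pressure(psub, temps), temps))
  if (is.numeric(psub)) {
    if (!is.null(names(psub))) {
      idx <- match(as.character(temps), names(psub))
      if (anyNA(idx))
        stop("psub names do not cover all isotherm temperatures",
             call. = FALSE)
      return(setNames(unname(psub[idx]), temps))
    }
    if (length(psub) == length(temps))
      return(setNames(psub, temps))
    if (length(psub) == 1)
      return(setNames(rep(psub, length(temps)), temps))
  }
  stop("psub must be a sublimation_model or a per-isotherm numeric",
       call. = FALSE)
}

.aard_by_T <- function(T, y_exp, y_calc) {
  temps <- sort(unique(T))
  setNames(vapply(temps, function(tt) {
    i <- T == tt
    aard(y_exp[i], y_calc[i])
  }, numeric(1)), temps)
}

.new_fit_result <- function(mode, params, aard_global, aard_by_T, n_points,
                            converged, objective_evals, extra = list()) {
  structure(c(list(mode = mode, params = params, aard_global = aard_global,
                   aard_by_T = aard_by_T, n_points = n_points,
                   converged = converged, objective_evals = objective_evals),
              extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mode = %s  (N = %d, %s, %d objective evals)\n",
              x$mode, x$n_points,
              if (x$converged) "converged" else "NOT converged",
              x$objective_evals))
  for (nm in names(x$params)) {
    v <- x$params[[nm]]
    cat(sprintf("  %-5s %s\n", nm,
                paste(signif(v, 6), collapse = "  ")))
  }
  cat(sprintf("  AARD global: %.2f%%\n", x$aard_global))
  for (i in seq_along(x$aard_by_T))
    cat(sprintf("  AARD at %s K: %.2f%%\n", names(x$aard_by_T)[i],
                x$aard_by_T[i]))
  invisible(x)
}

#' Fit Schmitt-Reid solute parameters (a2, b2) by AARD minimization
#'
#' Regresses the temperature-independent solute attraction and covolume of
#' the infinite-dilution modified-PR route against solubility data, with
#' sublimation pressures supplied per isotherm (this mode never fits them).
#' The objective is the pooled AARD; minimization is seeded multi-start
#' Nelder-Mead in log-parameter space. Pure-CO2 roots are independent of
#' (a2, b2) and are precomputed once per point.
#'
#' @param data Solubility dataset (columns `temperature_K`, `pressure_bar`,
#'   `y2`).
#' @param solute A [solute_properties()] (needs `v2s`).
#' @param psub A [sublimation_model()] or per-isotherm pressures, Pa.
#' @param n_starts Multi-start count (the AARD surface is non-convex).
#' @param seed RNG seed for the start jitter (results are reproducible
#'   given the seed).
#' @param max_eval Objective-evaluation cap per start.
#' @param poynting Poynting convention, as in [solubility()].
#' @param co2 CO2 critical set.
#' @return A `fit_result` with `params$a2` (Pa m^6 mol^-2), `params$b2`
#'   (m^3/mol), global and per-isotherm AARD.
#' @examples
#' ds <- generate_dataset(penicillin_fixture("penG"))
#' truth <- attr(ds, "truth")
#' fit_schmitt_reid(ds, truth$solute, truth$psub, n_starts = 2)
#' @export
fit_schmitt_reid <- function(data, solute, psub, n_starts = 8, seed = 1,
                             max_eval = 5000,
                             poynting = c("simplified", "full"),
                             co2 = co2_critical()) {
  poynting <- match.arg(poynting)
  d <- .dataset_cols(data)
  if (length(d$T) < 2)
    stop("under-determined: need >= 2 points for 2 parameters",
         call. = FALSE)
  temps <- sort(unique(d$T))
  ps_iso <- .psub_by_isotherm(psub, temps)
  ps <- ps_iso[as.character(d$T)]

  # Per-point precomputation: pure-CO2 PR root terms entering ln(phi2).
  pr <- eos_form("pr")
  pre <- lapply(seq_along(d$T), function(i) {
    p1 <- pure_params(pr, co2, d$T[i])
    fr <- .fluid_root(pr, p1, d$T[i], d$P[i])
    RT <- .R_GAS * d$T[i]
    L <- log((fr$v + (1 + sqrt(2)) * p1$b) / (fr$v + (1 - sqrt(2)) * p1$b))
    cc <- p1$a / (sqrt(8) * RT * p1$b) * L
    list(b1 = p1$b,
         q1 = fr$Z - 1,
         q2 = log(d$P[i] * (fr$v - p1$b) / RT),
         cc = cc,
         dd = 2 * cc / sqrt(p1$a))
  })
  b1 <- vapply(pre, `[[`, numeric(1), "b1")
  q1 <- vapply(pre, `[[`, numeric(1), "q1")
  q2 <- vapply(pre, `[[`, numeric(1), "q2")
  cc <- vapply(pre, `[[`, numeric(1), "cc")
  dd <- vapply(pre, `[[`, numeric(1), "dd")
  poy <- poynting_factor(solute$v2s, d$T, d$P, ps, full = poynting == "full")
  base <- ps / d$P * poy

  n_eval <- 0L
  y_calc_at <- function(a2, b2) {
    lnphi <- (b2 / b1) * (q1 + cc) - q2 - dd * sqrt(a2)
    base * exp(-lnphi)
  }
  objective <- function(par) {
    n_eval <<- n_eval + 1L
    yc <- y_calc_at(exp(par[1]), exp(par[2]))
    if (any(!is.finite(yc))) return(1e6)
    aard(d$y2, yc)
  }

  # Heuristic seed: b2 from the solid molar volume; a2 by inverting the
  # mean ln(phi2) required to reproduce the data at that b2.
  b2_0 <- solute$v2s
  target <- log(base / d$y2)
  sq_a2 <- mean(((b2_0 / b1) * (q1 + cc) - q2 - target) / dd)
  a2_0 <- if (is.finite(sq_a2) && sq_a2 > 0) sq_a2^2 else 1

  set.seed(seed)
  starts <- cbind(log(a2_0), log(b2_0))
  if (n_starts > 1) {
    jit <- cbind(rnorm(n_starts - 1, 0, 0.5), rnorm(n_starts - 1, 0, 0.2))
    starts <- rbind(starts, sweep(jit, 2, starts[1, ], "+"))
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- optim(starts[s, ], objective, method = "Nelder-Mead",
                 control = list(maxit = max_eval, reltol = 1e-10))
    if (is.null(best) || res$value < best$value) best <- res
  }
  a2 <- exp(best$par[1])
  b2 <- exp(best$par[2])
  y_calc <- y_calc_at(a2, b2)
  .new_fit_result(
    mode = "schmitt_reid",
    params = list(a2 = a2, b2 = b2, psub = ps_iso),
    aard_global = aard(d$y2, y_calc),
    aard_by_T = .aard_by_T(d$T, d$y2, y_calc),
    n_points = length(d$T),
    converged = best$convergence == 0,
    objective_evals = n_eval)
}

#' Fit the classical cubic-EoS route by AARD minimization
#'
#' Regresses the binary interaction parameter k12 — and, in
#' `psub_mode = "per_isotherm_free"`, one sublimation pressure per isotherm
#' — against solubility data through the compressed-gas model with the
#' chosen EoS and combining rule. The pooled-AARD objective is minimized
#' by seeded multi-start Nelder-Mead (k12 in linear space, sublimation
#' pressures in log space). Points where the forward model fails contribute
#' a large penalty (1e3 percentage points) instead of aborting.
#'
#' @inheritParams fit_schmitt_reid
#' @param eos An [eos_form()] or its name.
#' @param rule Combining rule for the cross attraction.
#' @param psub_mode `"per_isotherm_free"` (fit one P2sub per isotherm,
#'   the second-adjustable-parameter convention) or `"fixed"` (`psub`
#'   supplied, only k12 fitted).
#' @param psub Required when `psub_mode = "fixed"`.
#' @param k12_per_isotherm Fit one k12 per isotherm instead of a global one.
#' @return A `fit_result` with `params$k12` and `params$psub` (Pa,
#'   per isotherm), global and per-isotherm AARD.
#' @export
fit_classical <- function(data, solute, eos = eos_form("rk"),
                          rule = c("lorentz_berthelot", "van_der_waals"),
                          psub_mode = c("per_isotherm_free", "fixed"),
                          psub = NULL, k12_per_isotherm = FALSE,
                          n_starts = 8, seed = 1, max_eval = 2000,
                          poynting = c("simplified", "full"),
                          co2 = co2_critical()) {
  eos <- .as_eos(eos)
  rule <- match.arg(rule)
  psub_mode <- match.arg(psub_mode)
  poynting <- match.arg(poynting)
  if (is.null(solute$crit))
    stop("classical route needs solute$crit", call. = FALSE)
  d <- .dataset_cols(data)
  temps <- sort(unique(d$T))
  nT <- length(temps)
  n_k <- if (k12_per_isotherm) nT else 1L
  free_psub <- psub_mode == "per_isotherm_free"
  n_par <- n_k + if (free_psub) nT else 0L
  if (length(d$T) <= n_par)
    stop(sprintf("under-determined: %d points for %d parameters",
                 length(d$T), n_par), call. = FALSE)
  if (!free_psub && is.null(psub))
    stop("psub_mode = \"fixed\" needs psub", call. = FALSE)
  ps_fixed <- if (!free_psub) .psub_by_isotherm(psub, temps) else NULL
  iso_idx <- match(d$T, temps)

  n_eval <- 0L
  forward <- function(k12_vec, ps_iso) {
    vapply(seq_along(d$T), function(i) {
      tryCatch(
        solubility(d$T[i], d$P[i], solute, ps_iso[iso_idx[i]],
                   route = "classical", eos = eos, rule = rule,
                   k12 = k12_vec[if (k12_per_isotherm) iso_idx[i] else 1L],
                   poynting = poynting, co2 = co2),
        error = function(e) NA_real_)
    }, numeric(1))
  }
  unpack <- function(par) {
    k12 <- par[seq_len(n_k)]
    ps <- if (free_psub) exp(par[n_k + seq_len(nT)]) else unname(ps_fixed)
    list(k12 = k12, ps = ps)
  }
  objective <- function(par) {
    n_eval <<- n_eval + 1L
    pp <- unpack(par)
    if (any(abs(pp$k12) >= 1)) return(1e6)
    yc <- forward(pp$k12, pp$ps)
    terms <- ifelse(is.finite(yc), abs(d$y2 - yc) / d$y2, 10) # 1e3 % penalty
    100 * mean(terms)
  }

  # Seed the per-isotherm P2sub by inverting the model at the experimental
  # compositions for the start's k12 (exact if that k12 were the truth).
  psub_seed <- function(k12) {
    vapply(seq_len(nT), function(j) {
      i <- which(iso_idx == j)
      phi <- vapply(i, function(m) {
        tryCatch(phi2_classical(eos, d$T[m], d$P[m], d$y2[m], co2,
                                solute$crit, k12, rule),
                 error = function(e) NA_real_)
      }, numeric(1))
      poy <- poynting_factor(solute$v2s, d$T[i], d$P[i],
                             full = poynting == "full")
      v <- stats::median(d$y2[i] * d$P[i] * phi / poy, na.rm = TRUE)
      if (!is.finite(v) || v <= 0) 1e-6 else v
    }, numeric(1))
  }

  set.seed(seed)
  k12_starts <- c(0, runif(max(0, n_starts - 1), -0.3, 0.5))[seq_len(n_starts)]
  best <- NULL
  for (s in seq_len(n_starts)) {
    k0 <- rep(k12_starts[s], n_k)
    par0 <- k0
    if (free_psub) par0 <- c(par0, log(psub_seed(k12_starts[s])))
    res <- if (length(par0) == 1L) {
      # 1-D (global k12, fixed psub): bounded Brent search
      optim(par0, objective, method = "Brent", lower = -0.99, upper = 0.99,
            control = list(maxit = max_eval))
    } else {
      optim(par0, objective, method = "Nelder-Mead",
            control = list(maxit = max_eval, reltol = 1e-10))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  pp <- unpack(best$par)
  y_calc <- forward(pp$k12, pp$ps)
  ok <- all(is.finite(y_calc))
  .new_fit_result(
    mode = paste0("classical_", eos$name,
                  if (free_psub) "_psub_free" else "_psub_fixed"),
    params = list(k12 = pp$k12, psub = setNames(pp$ps, temps)),
    aard_global = if (ok) aard(d$y2, y_calc) else best$value,
    aard_by_T = if (ok) .aard_by_T(d$T, d$y2, y_calc) else
      setNames(rep(NA_real_, nT), temps),
    n_points = length(d$T),
    converged = best$convergence == 0 && ok,
    objective_evals = n_eval)
}
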
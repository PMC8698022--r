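#' Average absolute relative deviation (AARD)
#'
#' AARD(%) = 100/N sum |y_exp - y_calc| / y_exp — the fit-quality metric
#' used throughout supercritical-solubility modeling.
#'
#' @param y_exp Experimental values (> 0).
#' @param y_calc Calculated values (same length).
#' @return AARD, percent.
#' @examples
#' aard(c(1e-5, 2e-5), c(1.1e-5, 1.8e-5)) # 10
#' @export
aard <- function(y_exp, y_calc) {
  if (length(y_exp) != length(y_calc) || length(y_exp) < 1)
    stop("y_exp and y_calc must have equal length >= 1", call. = FALSE)
  if (any(y_exp <= 0)) stop("y_exp entries must be positive", call. = FALSE)
  100 * mean(abs(y_exp - y_calc) / y_exp)
}

# Extract columns with validation; density required when need_density.
.dataset_cols <- function(data, need_density = FALSE) {
  req <- c("temperature_K", "pressure_bar", "y2")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (need_density && !"density_kg_m3" %in% names(data))
    stop("dataset lacks density_kg_m3; use add_co2_density() or density_source = \"eos\"",
         call. = FALSE)
  list(T = data$temperature_K, P = data$pressure_bar * 1e5, y2 = data$y2,
       rho = if ("density_kg_m3" %in% names(data)) data$density_kg_m3 else NULL)
}

.r_squared <- function(fit) {
  r <- stats::residuals(fit)
  y <- r + stats::fitted(fit)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot > 0) 1 - sum(r^2) / ss_tot else 1
}

.rho_in_unit <- function(rho_kg_m3, density_unit) {
  switch(density_unit,
    kg_m3 = rho_kg_m3,
    mol_cm3 = rho_kg_m3 / .M_CO2 * 1e-6
  )
}

#' Mendez-Santiago-Teja (MST) correlation
#'
#' Pools all isotherms into the single-line least-squares fit
#' T ln(y2 P) = A' + B' rho + C' T with P in Pa, so the intercept C'
#' is directly the AS intercept of ln P2sub(Pa) = AS - dHs/(R T).
#'
#' @param data A solubility dataset (data frame with `temperature_K`,
#'   `pressure_bar`, `y2`, `density_kg_m3`).
#' @param density_unit `"kg_m3"` (default) or `"mol_cm3"`; only B' changes
#'   with the unit, and only C' is consumed downstream.
#' @return An object of class `mst_fit`: coefficients `A` (K),
#'   `B` (K per density unit), `C` (dimensionless), `aard` (%) on
#'   back-transformed solubilities, `r_squared`, `n`.
#' @export
mst_fit <- function(data, density_unit = c("kg_m3", "mol_cm3")) {
  density_unit <- match.arg(density_unit)
  d <- .dataset_cols(data, need_density = TRUE)
  if (length(d$T) < 3) stop("MST fit needs >= 3 points", call. = FALSE)
  rho <- .rho_in_unit(d$rho, density_unit)
  yy <- d$T * log(d$y2 * d$P)
  fit <- lm(yy ~ rho + d$T)
  if (anyNA(coef(fit))) stop("rank-deficient MST design", call. = FALSE)
  co <- unname(coef(fit))
  y_calc <- exp((co[1] + co[2] * rho) / d$T + co[3]) / d$P
  structure(list(A = co[1], B = co[2], C = co[3],
                 aard = aard(d$y2, y_calc),
                 r_squared = .r_squared(fit),
                 n = length(d$T), density_unit = density_unit),
            class = "mst_fit")
}

#' Bartle correlation
#'
#' Pooled least-squares fit of ln(y2 P / P_ref) = a + b/T + c (rho -
#' rho_ref) with P_ref = 1 bar and rho_ref = 700 kg/m^3. The slope b
#' encodes the sublimation enthalpy via dHs = -b R (exact identity).
#'
#' @inheritParams mst_fit
#' @param P_ref Reference pressure, Pa (default 1 bar).
#' @param rho_ref Reference density, kg/m^3.
#' @return An object of class `bartle_fit`: `a`, `b` (K), `c` (m^3/kg),
#'   `dHs` (J/mol), `aard` (%), `r_squared`, `n`.
#' @export
bartle_fit <- function(data, P_ref = 1e5, rho_ref = 700) {
  d <- .dataset_cols(data, need_density = TRUE)
  if (length(d$T) < 3) stop("Bartle fit needs >= 3 points", call. = FALSE)
  yy <- log(d$y2 * d$P / P_ref)
  invT <- 1 / d$T
  drho <- d$rho - rho_ref
  fit <- lm(yy ~ invT + drho)
  if (anyNA(coef(fit))) stop("rank-deficient Bartle design", call. = FALSE)
  co <- unname(coef(fit))
  y_calc <- exp(co[1] + co[2] * invT + co[3] * drho) * P_ref / d$P
  structure(list(a = co[1], b = co[2], c = co[3],
                 dHs = -co[2] * .R_GAS,
                 aard = aard(d$y2, y_calc),
                 r_squared = .r_squared(fit),
                 n = length(d$T)),
            class = "bartle_fit")
}

#' Consistency check of solubility data on the MST line
#'
#' Projects every point onto the MST linearization coordinate
#' T ln(y2 P) - C' T versus density; points whose standardized
#' (leave-one-out studentized) residual about the pooled line exceeds
#' `z_threshold` are flagged inconsistent. Studentization excludes each
#' point from its own scale estimate, so a gross outlier cannot mask
#' itself by inflating the pooled residual spread. The near-line collapse
#' is the MST model's data-consistency test; an exactly collinear dataset
#' flags nothing.
#'
#' @inheritParams mst_fit
#' @param fit An existing [mst_fit()]; fitted from `data` when `NULL`.
#' @param z_threshold Studentized-residual cutoff (default 2.0;
#'   `Inf` flags nothing).
#' @return List with `flagged` (logical per point), `z` (studentized
#'   residuals), `r_squared` of the pooled line, and the `fit` used.
#' @export
consistency_check <- function(data, fit = NULL, z_threshold = 2,
                              density_unit = c("kg_m3", "mol_cm3")) {
  density_unit <- match.arg(density_unit)
  if (is.null(fit)) fit <- mst_fit(data, density_unit = density_unit)
  d <- .dataset_cols(data, need_density = TRUE)
  rho <- .rho_in_unit(d$rho, fit$density_unit)
  ycoord <- d$T * log(d$y2 * d$P) - fit$C * d$T
  line <- lm(ycoord ~ rho)
  r <- stats::residuals(line)
  h <- stats::hatvalues(line)
  n <- length(r)
  sse <- sum(r^2)
  ss_tot <- sum((ycoord - mean(ycoord))^2)
  r2 <- if (ss_tot > 0) 1 - sse / ss_tot else 1
  # exact-collapse guard: residuals at rounding level carry no signal
  if (sqrt(sse / max(1, n - 2)) <= 1e-8 * max(sd(ycoord), 1)) {
    z <- rep(0, n)
  } else {
    s2_i <- pmax(0, (sse - r^2 / (1 - h)) / max(1, n - 3))
    z <- unname(r / sqrt(s2_i * (1 - h)))
    z[!is.finite(z)] <- 0
  }
  list(flagged = abs(z) > z_threshold, z = z, r_squared = r2, fit = fit)
}

#' Estimate a new sublimation-pressure model from solubility data
#'
#' The three-step EoS-independent procedure: (1) check data consistency on
#' the MST line and drop flagged points; (2) refit MST on the clean subset
#' — its intercept C' is the Clausius-Clapeyron intercept AS (P in Pa);
#' (3) fit Bartle on the clean subset — its slope gives the sublimation
#' enthalpy BS = -b R. The result is ln P2sub(Pa) = AS - BS/(R T).
#'
#' @inheritParams consistency_check
#' @param density_source `"column"` (require `density_kg_m3`) or `"eos"`
#'   (fill it from [co2_density()] with the chosen EoS).
#' @param eos EoS used when `density_source = "eos"`.
#' @return An object of class `psub_estimate`: `model`
#'   ([sublimation_model()]), `mst`, `bartle` (clean-subset fits),
#'   `flagged` (indices dropped), `consistency` (full-data check).
#' @examples
#' cfg <- penicillin_fixture("penG")
#' ds <- generate_dataset(cfg)
#' estimate_new_psub(ds, density_source = "eos")
#' @export
estimate_new_psub <- function(data, z_threshold = 2,
                              density_source = c("column", "eos"),
                              eos = eos_form("pr"),
                              density_unit = c("kg_m3", "mol_cm3")) {
  density_source <- match.arg(density_source)
  density_unit <- match.arg(density_unit)
  if (density_source == "eos" || !"density_kg_m3" %in% names(data))
    data <- add_co2_density(data, eos = eos)
  cc <- consistency_check(data, z_threshold = z_threshold,
                          density_unit = density_unit)
  keep <- !cc$flagged
  if (sum(keep) < 3)
    stop("fewer than 3 points survive the consistency check", call. = FALSE)
  clean <- data[keep, , drop = FALSE]
  mst <- mst_fit(clean, density_unit = density_unit)
  bart <- bartle_fit(clean)
  structure(list(model = sublimation_model(AS = mst$C, BS = bart$dHs),
                 mst = mst, bartle = bart,
                 flagged = which(cc$flagged), consistency = cc),
            class = "psub_estimate")
}

#' @export
print.psub_estimate <- function(x, ...) {
  cat("Sublimation-pressure estimate from solubility data\n")
  cat(sprintf("  dropped points: %s\n",
              if (length(x$flagged)) paste(x$flagged, collapse = ", ")
              else "none"))
  cat(sprintf("  MST:    C' = %.4g (AARD %.2f%%, R^2 %.4f)\n",
              x$mst$C, x$mst$aard, x$mst$r_squared))
  cat(sprintf("  Bartle: b = %.6g K -> dHs = %.1f kJ/mol (AARD %.2f%%)\n",
              x$bartle$b, x$bartle$dHs / 1000, x$bartle$aard))
  print(x$model)
  invisible(x)
}
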
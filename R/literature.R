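# Published regressed/estimated sublimation pressures for the two
# penicillin-CO2 systems, as reported by the original modeling studies
# (Gordillo et al. for penicillin G with RK and SRK; Ko et al. for
# penicillin V with a modified Clausius-Clapeyron estimate and PR).
.penG_psub <- data.frame(
  temperature_K = c(313.15, 323.15, 333.15),
  psub_rk_bar   = c(3.55e-12, 2.24e-11, 1.44e-10),
  aard_rk_pct   = c(23, 23, 23),
  psub_srk_bar  = c(2.82e-12, 4.57e-11, 3.09e-9),
  aard_srk_pct  = c(21, 21, 21)
)

.penV_psub <- data.frame(
  temperature_K     = c(314.85, 324.85, 334.85),
  psub_clausius_bar = c(5.53e-10, 1.54e-9, 3.83e-9),
  aard_clausius_pct = c(37.85, 42.46, 54.38),
  psub_pr_bar       = c(1.15e-10, 9.10e-9, 3.93e-7),
  aard_pr_pct       = c(36.23, 40.25, 41.30)
)

#' Published per-isotherm sublimation pressures for the penicillins
#'
#' The literature values obtained by treating the sublimation pressure as
#' a second adjustable parameter: for penicillin G the RK- and
#' SRK-regressed values (with the reported AARDs), for penicillin V the
#' modified-Clausius-Clapeyron estimate and the PR-regressed values.
#' These anchor the discrepancy and enthalpy reports.
#'
#' @param which `"penG"` or `"penV"`.
#' @return Data frame, one row per isotherm, pressures in bar.
#' @examples
#' psub_literature("penG")
#' @export
psub_literature <- function(which = c("penG", "penV")) {
  which <- match.arg(which)
  if (which == "penG") .penG_psub else .penV_psub
}

#' Discrepancy between the two literature sublimation-pressure columns
#'
#' Recomputes, per isotherm, [pressure_discrepancy()] between the two
#' published estimates, with the reference chosen as each study's
#' first-named column (SRK for penicillin G, PR for penicillin V).
#'
#' @inheritParams psub_literature
#' @return The [psub_literature()] table with a `discrepancy_pct` column.
#' @examples
#' round(psub_discrepancy_table("penG")$discrepancy_pct) # 26 51 95
#' @export
psub_discrepancy_table <- function(which = c("penG", "penV")) {
  which <- match.arg(which)
  tab <- psub_literature(which)
  tab$discrepancy_pct <- if (which == "penG") {
    pressure_discrepancy(tab$psub_srk_bar, tab$psub_rk_bar)
  } else {
    pressure_discrepancy(tab$psub_pr_bar, tab$psub_clausius_bar)
  }
  tab
}

#' Sublimation enthalpies implied by the literature pressure columns
#'
#' Fits a Clausius-Clapeyron line through each published per-isotherm
#' sublimation-pressure column and reports the implied sublimation
#' enthalpy BS (kJ/mol). For penicillin G these are the strikingly large
#' enthalpies (about 160 and 300 kJ/mol) that motivate estimating the
#' sublimation pressure independently of the EoS regression.
#'
#' @inheritParams psub_literature
#' @return Named numeric vector of enthalpies, kJ/mol, one per pressure
#'   column.
#' @examples
#' round(psub_enthalpy_table("penG"), 1) # rk 160.5, srk 302.8
#' @export
psub_enthalpy_table <- function(which = c("penG", "penV")) {
  which <- match.arg(which)
  tab <- psub_literature(which)
  cols <- grep("^psub_.*_bar$", names(tab), value = TRUE)
  out <- vapply(cols, function(cn) {
    fit_clausius(tab$temperature_K, tab[[cn]] * 1e5)$BS / 1000
  }, numeric(1))
  names(out) <- sub("^psub_(.*)_bar$", "\\1", cols)
  out
}

#' Published empirical-correlation coefficients for the penicillins
#'
#' The reported Mendez-Santiago-Teja and Bartle coefficients for the two
#' systems, with the derived sublimation-pressure models
#' (AS = C', BS = -b R): penicillin G ln P2sub(Pa) = 26.2 - 85300/(R T),
#' penicillin V ln P2sub(Pa) = 12.8 - 41900/(R T). The MST B' coefficient
#' is reported as printed; its density unit is ambiguous and B' is never
#' consumed downstream.
#'
#' @inheritParams psub_literature
#' @return List with `mst` (A, B, C, aard), `bartle` (a, b, c, aard,
#'   dHs_kJ_mol = -b R) and `model` (the implied [sublimation_model()]).
#' @examples
#' correlation_literature("penG")$bartle$dHs_kJ_mol # about 85.3
#' @export
correlation_literature <- function(which = c("penG", "penV")) {
  which <- match.arg(which)
  lit <- if (which == "penG") {
    list(mst = list(A = -11475.4, B = 165852.2, C = 26.2, aard = 24.6),
         bartle = list(a = 25.1, b = -10260.3, c = 1.2e-2, aard = 16.9))
  } else {
    list(mst = list(A = -5495.9, B = 73223.7, C = 12.8, aard = 17.01),
         bartle = list(a = 12.6, b = -5049.7, c = 5.05e-3, aard = 16.1))
  }
  lit$bartle$dHs_kJ_mol <- -lit$bartle$b * .R_GAS / 1000
  lit$model <- sublimation_model(AS = lit$mst$C,
                                 BS = -lit$bartle$b * .R_GAS)
  lit
}
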
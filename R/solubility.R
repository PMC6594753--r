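#' Spectrophotometric calibration line
#'
#' Ordinary least-squares line through (concentration, optical density) pairs,
#' e.g. peak absorbance at 311 nm of the drug dissolved in 1-octanol, which is
#' linear with concentration in the low-micromolar range.
#'
#' @param data Data frame with the calibration points.
#' @param conc,od Column names (tidy-eval) holding concentration (M) and
#'   optical density; defaults `conc_M` and `od`.
#'
#' @return An object of class `calibration_fit` with elements `slope` (OD per
#'   M), `intercept` (OD), `r_squared`, and the underlying `lm` fit.
#' @export
#' @examples
#' cal <- fit_calibration(data.frame(conc_M = c(0, 1e-6, 2e-6, 4e-6),
#'                                   od = c(0, 0.05, 0.10, 0.20)))
#' cal$slope  # 5e4 OD per M
fit_calibration <- function(data, conc = conc_M, od = od) {
  x <- dplyr::pull(data, {{ conc }})
  y <- dplyr::pull(data, {{ od }})
  if (length(x) < 3) abort("calibration needs at least 3 points")
  if (length(unique(x)) < 2) abort("calibration needs at least 2 distinct concentrations")
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, fit = fit, n = length(x)),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> OD = %.4g + %.4g * conc (r^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Concentration from optical density via a calibration line
#'
#' Inverts the calibration: `(od - intercept) / slope`. Optical densities
#' below the fitted intercept would imply a negative concentration and are an
#' error.
#'
#' @param od Optical density value(s).
#' @param cal A [fit_calibration()] result.
#' @return Concentration(s), M.
#' @export
extract_concentration <- function(od, cal) {
  if (!inherits(cal, "calibration_fit")) abort("`cal` must be a calibration_fit")
  if (any(od < cal$intercept)) {
    abort("optical density below the calibration intercept implies a negative concentration")
  }
  (od - cal$intercept) / cal$slope
}

#' Aqueous solubility from an extract concentration
#'
#' The extraction procedure concentrates the drug by the aqueous:organic
#' volume ratio (20-fold for a 20:1 extraction), so the aqueous solubility is
#' the measured extract concentration divided by that factor.
#'
#' @param extract_conc Drug concentration measured in the organic extract (M).
#' @param concentration_factor Volume ratio of the extraction (dimensionless).
#' @return Aqueous solubility (M).
#' @export
#' @examples
#' aqueous_solubility(1.2e-6, 20)  # 60 nM
aqueous_solubility <- function(extract_conc, concentration_factor) {
  if (any(extract_conc <= 0) || concentration_factor <= 0) {
    abort("extract concentration and concentration factor must be positive")
  }
  extract_conc / concentration_factor
}

#' Distribution coefficient between a solvent and water
#'
#' Ratio of equilibrium solubilities in an organic solvent and in aqueous
#' buffer at a stated pH, e.g. the octanol/water distribution coefficient that
#' constrains `k_in/k_out` in the ensemble fits.
#'
#' @param s_solvent Solubility in the organic solvent (M).
#' @param s_aq Aqueous solubility (M).
#' @return A tibble with `d` and `log_d`.
#' @export
#' @examples
#' distribution_coefficient(3.9e-3, 6.2e-8)  # logD = 4.8
distribution_coefficient <- function(s_solvent, s_aq) {
  if (any(s_solvent <= 0) || any(s_aq <= 0)) abort("solubilities must be positive")
  d <- s_solvent / s_aq
  tibble(d = d, log_d = log10(d))
}

#' Two-point van't Hoff enthalpy of solution
#'
#' `dH = R * T1 * T2 / (T2 - T1) * ln(S(T2)/S(T1))`, with
#' R = 8.31 J mol^-1 K^-1. The formula is symmetric in the two measurements.
#'
#' @param s1,s2 Solubilities (M) at temperatures `t1`, `t2`.
#' @param t1,t2 Temperatures (K), distinct.
#' @param ph1,ph2 Optional pH of each measurement; a warning is raised if they
#'   differ.
#' @return Standard enthalpy of solution (J/mol).
#' @export
#' @examples
#' enthalpy_of_solution(62e-9, 298, 138e-9, 310) / 1000  # +51.2 kJ/mol
enthalpy_of_solution <- function(s1, t1, s2, t2, ph1 = NULL, ph2 = NULL) {
  if (t1 <= 0 || t2 <= 0 || s1 <= 0 || s2 <= 0) {
    abort("solubilities and absolute temperatures must be positive")
  }
  if (t1 == t2) abort("the two temperatures must differ")
  if (!is.null(ph1) && !is.null(ph2) && ph1 != ph2) {
    warn("solubilities measured at different pH; the van't Hoff estimate mixes protonation states")
  }
  .const$R_gas * t1 * t2 / (t2 - t1) * log(s2 / s1)
}

#' Standard free energy of solution
#'
#' `dG = -R * T * ln(S)` with S in mol/L against the implicit 1 M standard
#' state; R = 8.31 J mol^-1 K^-1.
#'
#' @param s Solubility (M).
#' @param t Temperature (K).
#' @return Standard free energy of solution (J/mol).
#' @export
#' @examples
#' gibbs_of_solution(62e-9, 298) / 1000  # +41.1 kJ/mol
gibbs_of_solution <- function(s, t) {
  if (any(s <= 0) || any(t <= 0)) abort("solubility and temperature must be positive")
  -.const$R_gas * t * log(s)
}

#' Entropic term of the solution process
#'
#' `T * dS = dH - dG` at the temperature of the free-energy estimate.
#'
#' @param dh Enthalpy of solution (J/mol).
#' @param dg Free energy of solution (J/mol).
#' @return `T*dS` (J/mol).
#' @export
entropy_term <- function(dh, dg) dh - dg

#' Full two-temperature solution thermodynamics
#'
#' Convenience wrapper combining [enthalpy_of_solution()],
#' [gibbs_of_solution()] and [entropy_term()] for a pair of
#' solubility-temperature measurements.
#'
#' @inheritParams enthalpy_of_solution
#' @return A one-row tibble with `dh`, `dg_t1`, `dg_t2`, `tds_t1` (J/mol) and
#'   the inputs.
#' @export
#' @examples
#' solution_thermodynamics(62e-9, 298, 138e-9, 310)
solution_thermodynamics <- function(s1, t1, s2, t2) {
  dh <- enthalpy_of_solution(s1, t1, s2, t2)
  dg1 <- gibbs_of_solution(s1, t1)
  dg2 <- gibbs_of_solution(s2, t2)
  tibble(s1 = s1, t1 = t1, s2 = s2, t2 = t2,
         dh = dh, dg_t1 = dg1, dg_t2 = dg2, tds_t1 = entropy_term(dh, dg1))
}
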
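#' Stoichiometric and physical parameters of the fermentation scenario model
#'
#' Collects every constant the lumped-network solver uses: the biomass equation
#' (mass per Cmol, degree of reduction, cofactor and CO2 coupling), the
#' ATP-coupled growth yield, per-reaction net ATP coefficients, the ethanol
#' evaporation constant, and the Rubisco CO2 half-saturation.
#'
#' Biosynthesis is lumped Verduyn-style: forming one Cmol of biomass from
#' hexose carbon produces `n_nadh` mol NADH, consumes `n_nadph` mol NADPH, and
#' releases `n_co2_biomass` mol CO2. When `n_co2_biomass` is not supplied it is
#' derived from the electron balance of the biomass reaction,
#' `4 (1 + n_co2_biomass) = gamma_biomass + 2 n_nadh - 2 n_nadph`,
#' so that every solved scenario closes the degree-of-reduction balance
#' exactly.
#'
#' @param biomass_carbon_content g dry weight per Cmol biomass (default 24.6).
#' @param gamma_biomass electrons per Cmol biomass (degree of reduction,
#'   default 4.2).
#' @param n_nadh mol NADH produced in biosynthesis per Cmol biomass.
#' @param n_nadph mol NADPH consumed in biosynthesis per Cmol biomass.
#' @param n_co2_biomass mol CO2 released in biosynthesis per Cmol biomass;
#'   `NULL` (default) derives it from the electron balance.
#' @param y_atp Cmol biomass formed per mol ATP (biomass yield on ATP). May be
#'   0, the zero-growth limit.
#' @param atp_coeffs named list of per-reaction net ATP coefficients:
#'   `ferment` (+2 per hexose), `glycerol` (-1 per glycerol), `rubisco`
#'   (+1 per Ru5P carboxylated), `oxppp_hexose` (-1 per hexose entering the
#'   oxidative PPP), `nonoxppp_ru5p` (-7/6 per Ru5P made from glycolytic
#'   intermediates).
#' @param k_evap first-order ethanol evaporation constant, h^-1 (default
#'   0.008).
#' @param K_co2 Rubisco half-saturation constant for dissolved CO2, mM
#'   (default 0.26).
#' @param maintenance_atp mol ATP h^-1 per g biomass (default 0).
#' @param henry_co2 CO2 solubility, mM per atm of CO2 partial pressure
#'   (default 29.9, water at 30 degrees C), used only to translate a sparging
#'   gas composition into a dissolved concentration.
#' @return an object of class `stoich_params` (a validated named list).
#' @seealso [read_stoich_params()], [solve_scenario()], [redox_model()]
#' @export
stoich_params <- function(biomass_carbon_content = 24.6,
                          gamma_biomass = 4.2,
                          n_nadh = 0.230,
                          n_nadph = 0.150,
                          n_co2_biomass = NULL,
                          y_atp = 0.430,
                          atp_coeffs = list(),
                          k_evap = 0.008,
                          K_co2 = 0.26,
                          maintenance_atp = 0,
                          henry_co2 = 29.9) {
  default_atp <- list(ferment = 2, glycerol = -1, rubisco = 1,
                      oxppp_hexose = -1, nonoxppp_ru5p = -7 / 6)
  atp <- utils::modifyList(default_atp, as.list(atp_coeffs))
  if (!all(names(atp) %in% names(default_atp)))
    stop_input(paste0("unknown atp_coeffs entries: ",
                      paste(setdiff(names(atp), names(default_atp)),
                            collapse = ", ")))
  if (is.null(n_co2_biomass))
    n_co2_biomass <- (gamma_biomass + 2 * n_nadh - 2 * n_nadph) / 4 - 1
  p <- structure(list(
    biomass_carbon_content = biomass_carbon_content,
    gamma_biomass = gamma_biomass,
    n_nadh = n_nadh,
    n_nadph = n_nadph,
    n_co2_biomass = n_co2_biomass,
    y_atp = y_atp,
    atp_coeffs = atp,
    k_evap = k_evap,
    K_co2 = K_co2,
    maintenance_atp = maintenance_atp,
    henry_co2 = henry_co2), class = "stoich_params")
  validate_stoich_params(p)
}

validate_stoich_params <- function(p) {
  num <- unlist(p[setdiff(names(p), "atp_coeffs")])
  if (!all(is.finite(num)) || !all(is.finite(unlist(p$atp_coeffs))))
    stop_input("all stoichiometric parameters must be finite")
  if (p$n_nadh <= 0) stop_input("n_nadh must be > 0")
  if (p$n_nadph <= 0) stop_input("n_nadph must be > 0")
  if (p$y_atp < 0) stop_input("y_atp must be >= 0")
  if (p$k_evap < 0) stop_input("k_evap must be >= 0")
  if (p$K_co2 <= 0) stop_input("K_co2 must be > 0")
  if (p$biomass_carbon_content <= 0)
    stop_input("biomass_carbon_content must be > 0")
  if (p$maintenance_atp < 0) stop_input("maintenance_atp must be >= 0")
  if (p$henry_co2 <= 0) stop_input("henry_co2 must be > 0")
  p
}

#' @export
print.stoich_params <- function(x, ...) {
  cat("Stoichiometric parameters (per Cmol biomass unless noted)\n")
  cat(sprintf("  biomass: %.3g g/Cmol, gamma = %.4g e-/Cmol, CO2 release = %.4g\n",
              x$biomass_carbon_content, x$gamma_biomass, x$n_co2_biomass))
  cat(sprintf("  cofactors: NADH +%.4g, NADPH -%.4g\n", x$n_nadh, x$n_nadph))
  cat(sprintf("  Y_ATP = %.4g Cmol/mol ATP (%.3g g/mol ATP), maintenance = %.3g\n",
              x$y_atp, x$y_atp * x$biomass_carbon_content, x$maintenance_atp))
  cat(sprintf("  k_evap = %.3g h^-1, K_CO2 = %.3g mM, Henry = %.3g mM/atm\n",
              x$k_evap, x$K_co2, x$henry_co2))
  cat("  ATP coefficients:",
      paste(sprintf("%s %+.4g", names(x$atp_coeffs), unlist(x$atp_coeffs)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read or write model parameters as a YAML config file
#'
#' The file keys mirror the arguments of [stoich_params()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path file path.
#' @param params a `stoich_params` object (for writing).
#' @return `read_stoich_params()` returns a `stoich_params` object;
#'   `write_stoich_params()` returns `path` invisibly.
#' @export
read_stoich_params <- function(path) {
  if (!file.exists(path)) stop_input(paste0("parameter file not found: ", path))
  cfg <- yaml::read_yaml(path)
  known <- names(formals(stoich_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_input(paste0("unknown parameter keys in ", path, ": ",
                      paste(bad, collapse = ", ")))
  do.call(stoich_params, cfg)
}

#' @rdname read_stoich_params
#' @export
write_stoich_params <- function(params, path) {
  stopifnot(inherits(params, "stoich_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' Fractional saturation of Rubisco with dissolved CO2
#'
#' Michaelis-Menten saturation `c / (K + c)`. Used only to cap the attainable
#' Rubisco flux; the balance equations themselves are never rescaled by it.
#'
#' @param c_dissolved dissolved CO2 concentration in mM, or `"saturating"`
#'   (equivalently `Inf`).
#' @param K_co2 half-saturation constant in mM (default 0.26, the low-affinity
#'   bacterial form-II enzyme used here).
#' @return saturation fraction in `[0, 1]`.
#' @export
co2_saturation_factor <- function(c_dissolved, K_co2 = 0.26) {
  if (identical(c_dissolved, "saturating")) c_dissolved <- Inf
  if (!is.numeric(c_dissolved) || any(c_dissolved < 0))
    stop_domain("dissolved CO2 concentration must be >= 0 or \"saturating\"")
  if (K_co2 <= 0) stop_domain("K_co2 must be > 0")
  ifelse(is.infinite(c_dissolved), 1, c_dissolved / (K_co2 + c_dissolved))
}

#' Dissolved CO2 implied by the sparging-gas composition
#'
#' Henry's-law equilibrium concentration for a given CO2 volume fraction in
#' the sparging gas at 1 atm total pressure.
#'
#' @param co2_fraction CO2 volume fraction of the gas (0.10 for a 10 percent
#'   CO2 blend).
#' @param henry_co2 solubility in mM per atm (default 29.9 at 30 degrees C).
#' @return dissolved CO2 in mM.
#' @export
dissolved_co2 <- function(co2_fraction, henry_co2 = 29.9) {
  if (any(co2_fraction < 0) || any(co2_fraction > 1))
    stop_domain("co2_fraction must lie in [0, 1]")
  co2_fraction * henry_co2
}
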
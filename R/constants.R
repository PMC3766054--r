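# Physical constants used throughout. Molecular masses in g/mol; electrons per
# mol are degrees of reduction times carbon number.
MW_HEXOSE   <- 180  # glucose and galactose pooled as one hexose species
MW_ETHANOL  <- 46.07
MW_GLYCEROL <- 92.09

E_PER_HEXOSE   <- 24  # 4 e- per C, 6 C
E_PER_ETHANOL  <- 12
E_PER_GLYCEROL <- 14

#' Molar volume of an ideal gas at bioreactor conditions
#'
#' Litres per mole at 30 degrees C and 1 atm, used to convert off-gas CO2
#' volume fractions into molar rates. Exposed so gas-balance arithmetic can be
#' reproduced at other temperatures.
#'
#' @param temperature_c gas temperature in degrees Celsius.
#' @return molar volume in l mol^-1.
#' @export
molar_volume <- function(temperature_c = 30) {
  0.082057 * (273.15 + temperature_c) / 1 * 1  # R*T/p, p = 1 atm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("redoxferm_domain_error", "error")))
}

stop_infeasible <- function(balance, detail = "") {
  stop(errorCondition(
    sprintf("scenario infeasible: %s balance cannot be satisfied%s", balance,
            if (nzchar(detail)) paste0(" (", detail, ")") else ""),
    class = c("redoxferm_infeasible", "error"), balance = balance))
}

stop_input <- function(msg) {
  stop(errorCondition(msg, class = c("redoxferm_input_error", "error")))
}

# Round to one significant figure (headline projection convention).
signif1 <- function(x) signif(x, 1)
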
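#' Chemostat steady-state records
#'
#' A `chemostat_records` object is a data frame with one row per steady state
#' (replicate culture) and the columns:
#' `replicate_id`, `dilution_rate` (h^-1), `glucose_in`, `galactose_in`,
#' `glucose_res`, `galactose_res`, `biomass`, `ethanol`, `glycerol` (all
#' g l^-1, broth concentrations as measured), `gas_flow` (l h^-1 per l
#' broth), `co2_in`, `co2_out` (volume fractions).
#'
#' @param path tab- or comma-delimited text file with the documented header.
#' @return a validated `chemostat_records` data frame.
#' @export
read_chemostat_records <- function(path) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  d <- utils::read.delim(path, sep = "", check.names = FALSE)
  as_chemostat_records(d, source = path)
}

chemostat_columns <- c("replicate_id", "dilution_rate", "glucose_in",
                       "galactose_in", "glucose_res", "galactose_res",
                       "biomass", "ethanol", "glycerol", "gas_flow",
                       "co2_in", "co2_out")

#' @rdname read_chemostat_records
#' @param d a data frame with the documented columns.
#' @param source label used in validation messages.
#' @export
as_chemostat_records <- function(d, source = "chemostat records") {
  missing_cols <- setdiff(chemostat_columns, names(d))
  if (length(missing_cols))
    stop_input(paste0(source, ": missing columns: ",
                      paste(missing_cols, collapse = ", ")))
  d <- d[chemostat_columns]
  check_row <- function(i) {
    r <- d[i, ]
    msgs <- character()
    if (!is.finite(r$dilution_rate) || r$dilution_rate <= 0)
      msgs <- c(msgs, "dilution_rate must be > 0")
    num <- unlist(r[c("glucose_in", "galactose_in", "glucose_res",
                      "galactose_res", "biomass", "ethanol", "glycerol",
                      "gas_flow")])
    if (any(!is.finite(num)) || any(num < 0))
      msgs <- c(msgs, "concentrations and gas_flow must be finite and >= 0")
    if (r$glucose_res > r$glucose_in + 1e-9 ||
        r$galactose_res > r$galactose_in + 1e-9)
      msgs <- c(msgs, "residual sugar exceeds inlet sugar")
    if (r$co2_in < 0 || r$co2_in > 1 || r$co2_out < 0 || r$co2_out > 1)
      msgs <- c(msgs, "co2 fractions must lie in [0, 1]")
    if (length(msgs))
      stop_input(sprintf("%s, row %d: %s", source, i,
                         paste(msgs, collapse = "; ")))
  }
  for (i in seq_len(nrow(d))) check_row(i)
  structure(d, class = c("chemostat_records", "data.frame"))
}

#' Batch fermentation time series
#'
#' A `batch_series` object is a data frame with columns `replicate_id`,
#' `time` (h, strictly increasing within a replicate), `biomass`, `sugar`,
#' `ethanol`, `glycerol` (g l^-1, broth as measured).
#'
#' @param path delimited text file.
#' @return a validated `batch_series` data frame.
#' @export
read_batch_series <- function(path) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  as_batch_series(utils::read.delim(path, sep = ""), source = path)
}

batch_columns <- c("replicate_id", "time", "biomass", "sugar", "ethanol",
                   "glycerol")

#' @rdname read_batch_series
#' @param d a data frame with the documented columns.
#' @param source label used in validation messages.
#' @export
as_batch_series <- function(d, source = "batch series") {
  missing_cols <- setdiff(batch_columns, names(d))
  if (length(missing_cols))
    stop_input(paste0(source, ": missing columns: ",
                      paste(missing_cols, collapse = ", ")))
  d <- d[batch_columns]
  for (id in unique(d$replicate_id)) {
    s <- d[d$replicate_id == id, ]
    if (nrow(s) < 4)
      stop_input(sprintf("%s, replicate %s: need >= 4 samples", source, id))
    if (any(diff(s$time) <= 0))
      stop_input(sprintf("%s, replicate %s: time must be strictly increasing",
                         source, id))
    if (any(unlist(s[c("biomass", "sugar", "ethanol", "glycerol")]) < 0))
      stop_input(sprintf("%s, replicate %s: negative concentrations", source, id))
  }
  structure(d, class = c("batch_series", "data.frame"))
}

#' Steady-state ethanol evaporation correction for chemostats
#'
#' Ethanol is stripped from the broth by the sparging gas with first-order
#' rate constant `k_evap`. At steady state the volumetric production rate is
#' `(D + k_evap) * C`, so the concentration that yield arithmetic should use
#' is `C * (D + k_evap) / D`.
#'
#' @param ethanol_conc measured broth ethanol, g l^-1.
#' @param dilution_rate chemostat dilution rate D, h^-1 (> 0).
#' @param k_evap first-order evaporation constant, h^-1 (default 0.008).
#' @return production-equivalent ethanol concentration, g l^-1.
#' @export
correct_evaporation_chemostat <- function(ethanol_conc, dilution_rate,
                                          k_evap = 0.008) {
  if (any(ethanol_conc < 0) || k_evap < 0)
    stop_domain("ethanol_conc and k_evap must be >= 0")
  if (any(dilution_rate <= 0)) stop_domain("dilution_rate must be > 0")
  ethanol_conc * (dilution_rate + k_evap) / dilution_rate
}

#' Cumulative produced ethanol in a batch culture, correcting evaporation
#'
#' Integrates the first-order loss term over the sampled trajectory:
#' `produced(t) = C(t) + k_evap * integral_0^t C(tau) dtau`, with the
#' integral evaluated by the trapezoidal rule on the sample grid.
#'
#' @param time sample times, h, strictly increasing.
#' @param ethanol_conc measured broth ethanol at each time, g l^-1.
#' @param k_evap evaporation constant, h^-1.
#' @return vector of cumulative produced ethanol (g l^-1) per time point.
#' @export
correct_evaporation_batch <- function(time, ethanol_conc, k_evap = 0.008) {
  if (length(time) != length(ethanol_conc))
    stop_input("time and ethanol_conc must have equal length")
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  if (any(ethanol_conc < 0) || k_evap < 0)
    stop_domain("ethanol_conc and k_evap must be >= 0")
  n <- length(time)
  integral <- c(0, cumsum(diff(time) *
                            (ethanol_conc[-n] + ethanol_conc[-1]) / 2))
  ethanol_conc + k_evap * integral
}

#' Yields from a chemostat steady state
#'
#' Sugar consumption pools glucose and galactose as one hexose species
#' (180 g mol^-1); ethanol is evaporation-corrected with
#' [correct_evaporation_chemostat()] unless `correct_evaporation = FALSE`.
#'
#' @param records a `chemostat_records` data frame (one row per replicate).
#' @param params a [stoich_params()] (supplies `k_evap`).
#' @param correct_evaporation apply the steady-state correction (default
#'   TRUE).
#' @return a [yield_set()] with one row per record.
#' @export
chemostat_yields <- function(records, params = stoich_params(),
                             correct_evaporation = TRUE) {
  records <- as_chemostat_records(as.data.frame(records))
  consumed_g <- (records$glucose_in - records$glucose_res) +
    (records$galactose_in - records$galactose_res)
  if (any(consumed_g <= 0)) stop_input("no sugar consumed in some record")
  consumed_mol <- consumed_g / MW_HEXOSE
  k <- if (correct_evaporation) params$k_evap else 0
  ethanol <- correct_evaporation_chemostat(records$ethanol,
                                           records$dilution_rate, k)
  yield_set(Y_biomass = records$biomass / consumed_g,
            Y_ethanol = (ethanol / MW_ETHANOL) / consumed_mol,
            Y_glycerol = (records$glycerol / MW_GLYCEROL) / consumed_mol,
            replicate = records$replicate_id,
            corrected = correct_evaporation)
}

#' Yields from a batch fermentation time series
#'
#' Yields are computed from total amounts converted between the first and
#' last sample, with cumulative ethanol production reconstructed by
#' [correct_evaporation_batch()].
#'
#' @param series a `batch_series` data frame (may hold several replicates).
#' @param params a [stoich_params()].
#' @param correct_evaporation apply the evaporation correction (default TRUE).
#' @return a [yield_set()] with one row per replicate.
#' @export
batch_yields <- function(series, params = stoich_params(),
                         correct_evaporation = TRUE) {
  series <- as_batch_series(as.data.frame(series))
  ids <- unique(series$replicate_id)
  k <- if (correct_evaporation) params$k_evap else 0
  res <- lapply(ids, function(id) {
    s <- series[series$replicate_id == id, ]
    consumed_g <- s$sugar[1] - s$sugar[nrow(s)]
    if (consumed_g <= 0)
      stop_input(sprintf("replicate %s: no sugar consumed", id))
    produced <- correct_evaporation_batch(s$time, s$ethanol, k)
    c(Y_biomass = (s$biomass[nrow(s)] - s$biomass[1]) / consumed_g,
      Y_ethanol = ((produced[length(produced)] - produced[1]) / MW_ETHANOL) /
        (consumed_g / MW_HEXOSE),
      Y_glycerol = ((s$glycerol[nrow(s)] - s$glycerol[1]) / MW_GLYCEROL) /
        (consumed_g / MW_HEXOSE))
  })
  m <- do.call(rbind, res)
  yield_set(m[, "Y_biomass"], m[, "Y_ethanol"], m[, "Y_glycerol"],
            replicate = ids, corrected = correct_evaporation)
}

#' Net volumetric CO2 evolution rate from off-gas analysis
#'
#' @param records a `chemostat_records` data frame.
#' @param temperature_c gas temperature for the molar volume (default 30).
#' @param tolerance tolerated negative net evolution before flagging
#'   apparent net fixation (volume-fraction units).
#' @return data frame with `replicate_id`, `co2_evolution` (mmol CO2 h^-1 per
#'   l broth) and `net_fixation_flag` (outlet below inlet beyond tolerance:
#'   apparent net CO2 fixation).
#' @export
net_co2_evolution <- function(records, temperature_c = 30, tolerance = 1e-6) {
  records <- as_chemostat_records(as.data.frame(records))
  if (any(records$gas_flow <= 0)) stop_input("gas_flow must be > 0")
  dfrac <- records$co2_out - records$co2_in
  evo <- records$gas_flow * dfrac / molar_volume(temperature_c) * 1000  # mmol
  flag <- dfrac < -tolerance
  if (any(flag))
    warning("net CO2 fixation exceeds evolution in some records")
  data.frame(replicate_id = records$replicate_id, co2_evolution = evo,
             net_fixation_flag = flag)
}

#' Carbon and electron recovery of a yield set
#'
#' Reconciliation check: fractions of substrate carbon and of available
#' electrons recovered in biomass, ethanol, glycerol and CO2.
#'
#' @param yields a [yield_set()] (replicates averaged).
#' @param co2_yield net CO2 yield in mol per mol hexose. If `NULL` it is
#'   estimated from the fermentation coupling (CO2 = ethanol) plus the
#'   biosynthetic release implied by `params`.
#' @param params a [stoich_params()].
#' @param band PASS band for both recoveries (default 0.95 to 1.05).
#' @return list with `carbon_recovery`, `electron_recovery`, `pass`.
#' @export
balance_check <- function(yields, co2_yield = NULL, params = stoich_params(),
                          band = c(0.95, 1.05)) {
  ym <- yield_means(yields)
  x_cmol <- ym[["Y_biomass"]] * MW_HEXOSE / params$biomass_carbon_content
  if (is.null(co2_yield))
    co2_yield <- ym[["Y_ethanol"]] +
      x_cmol * (params$n_co2_biomass + params$n_nadph / 2)
  carbon <- (2 * ym[["Y_ethanol"]] + 3 * ym[["Y_glycerol"]] + x_cmol +
               co2_yield) / 6
  electron <- (E_PER_ETHANOL * ym[["Y_ethanol"]] +
                 E_PER_GLYCEROL * ym[["Y_glycerol"]] +
                 params$gamma_biomass * x_cmol) / E_PER_HEXOSE
  list(carbon_recovery = carbon, electron_recovery = electron,
       pass = carbon >= band[1] && carbon <= band[2] &&
         electron >= band[1] && electron <= band[2])
}

#' Compare yields of two strains with a two-sample t-test
#'
#' @param ref,eng [yield_set()]s of replicate yields for the reference and
#'   engineered strain (>= 2 replicates each).
#' @param alpha significance threshold (default 0.02).
#' @return a `strain_comparison`: data frame with one row per yield holding
#'   the reference and engineered means (with mean deviations), the percent
#'   change (full precision and rounded to integer percent), the equal-
#'   variance two-sided t-test p-value, and significance at `alpha`.
#'   Yields with a zero reference mean get `NA` percent change and a flag.
#' @export
compare_strains <- function(ref, eng, alpha = 0.02) {
  stopifnot(inherits(ref, "yield_set"), inherits(eng, "yield_set"))
  if (nrow(ref) < 2 || nrow(eng) < 2)
    stop_input("need >= 2 replicates per strain")
  cols <- c("Y_biomass", "Y_ethanol", "Y_glycerol")
  rows <- lapply(cols, function(cl) {
    a <- ref[[cl]]; b <- eng[[cl]]
    p <- if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0  # degenerate: no within-arm spread
    } else stats::t.test(b, a, var.equal = TRUE)$p.value
    pc <- if (mean(a) > 0) 100 * (mean(b) - mean(a)) / mean(a) else NA_real_
    data.frame(yield = cl,
               ref_mean = mean(a), ref_mean_deviation = mean_deviation(a),
               eng_mean = mean(b), eng_mean_deviation = mean_deviation(b),
               percent_change = pc,
               percent_change_rounded = round(pc),
               p_value = p,
               significant = is.finite(p) && p < alpha,
               undefined_change = !(mean(a) > 0))
  })
  structure(do.call(rbind, rows), alpha = alpha,
            class = c("strain_comparison", "data.frame"))
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("Strain comparison (t-test, alpha = %g)\n", attr(x, "alpha")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s %.3g +/- %.2g -> %.3g +/- %.2g : %+d%% (p = %.3g)%s\n",
                x$yield[i], x$ref_mean[i], x$ref_mean_deviation[i],
                x$eng_mean[i], x$eng_mean_deviation[i],
                x$percent_change_rounded[i], x$p_value[i],
                if (x$significant[i]) " *" else ""))
  }
  invisible(x)
}
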
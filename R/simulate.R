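#' Load a packaged chemostat culture condition
#'
#' The package ships, as plain YAML data, the four anaerobic chemostat
#' conditions of the study design (2 strains x 2 sparging gases; sugar-limited
#' at D = 0.05 h^-1 on 12.5 + 12.5 g l^-1 glucose/galactose), each encoded by
#' its steady-state yields and off-gas setting. [generate_chemostat()] turns a
#' condition into synthetic replicate records.
#'
#' @param condition one of `"reference_n2"`, `"reference_co2"`,
#'   `"prk_rubisco_n2"`, `"prk_rubisco_co2"`.
#' @param file fixture file (default: the packaged one).
#' @param params_file stoichiometric parameter file (default: the packaged
#'   defaults).
#' @return a `generator_config` list.
#' @export
chemostat_fixture <- function(condition = c("reference_n2", "reference_co2",
                                            "prk_rubisco_n2",
                                            "prk_rubisco_co2"),
                              file = system.file("extdata",
                                                 "chemostat_conditions.yml",
                                                 package = "redoxferm"),
                              params_file = system.file("extdata",
                                                        "params_default.yml",
                                                        package = "redoxferm")) {
  condition <- match.arg(condition)
  cfg <- yaml::read_yaml(file)
  cond <- cfg$conditions[[condition]]
  if (is.null(cond)) stop_input(paste0("condition not in fixture: ", condition))
  out <- c(cfg$shared, cond)
  out$condition <- condition
  out$params <- read_stoich_params(params_file)
  if (!is.null(cond$reference_condition)) {
    rc <- cfg$conditions[[cond$reference_condition]]
    out$reference_yields <- yield_set(rc$Y_biomass, rc$Y_ethanol, rc$Y_glycerol)
  }
  structure(out, class = "generator_config")
}

#' @rdname chemostat_fixture
#' @param strain `"reference"` or `"prk_rubisco"`.
#' @export
batch_fixture <- function(strain = c("reference", "prk_rubisco"),
                          file = system.file("extdata", "batch_conditions.yml",
                                             package = "redoxferm"),
                          params_file = system.file("extdata",
                                                    "params_default.yml",
                                                    package = "redoxferm")) {
  strain <- match.arg(strain)
  cfg <- yaml::read_yaml(file)
  cond <- cfg$conditions[[strain]]
  if (is.null(cond)) stop_input(paste0("strain not in fixture: ", strain))
  out <- c(cfg$shared, cond)
  out$condition <- strain
  out$params <- read_stoich_params(params_file)
  structure(out, class = "generator_config")
}

# Parameterise a chemostat condition so the scenario solver reproduces its
# yields exactly. Reference conditions calibrate directly; engineered
# conditions inherit n_nadh/n_nadph from the matching reference calibration
# and set the Rubisco capacity from the NADH balance.
condition_params <- function(config) {
  p0 <- config$params
  own <- yield_set(config$Y_biomass, config$Y_ethanol, config$Y_glycerol)
  if (identical(config$mode, "reference")) {
    p <- calibrate_stoich(p0, own)
    list(params = p, mode = "reference", capacity = 0,
         flux = solve_scenario(p, "reference"))
  } else {
    if (is.null(config$reference_yields))
      stop_input("engineered condition needs reference_yields for calibration")
    p_ref <- calibrate_stoich(p0, config$reference_yields)
    cal <- calibrate_engineered(p_ref, own)
    list(params = cal$params, mode = "prk_rubisco", capacity = cal$capacity,
         flux = solve_scenario(cal$params, "prk_rubisco",
                               rubisco_capacity = cal$capacity))
  }
}

# Engineered-mode analogue of calibrate_stoich: n_nadh and n_nadph are fixed
# (shared biosynthesis with the reference strain); the Rubisco flux follows
# from the NADH balance, the biosynthetic CO2 release from carbon closure,
# y_atp from the ATP balance and gamma from electron closure.
calibrate_engineered <- function(params_ref, yields) {
  ym <- yield_means(yields)
  x <- ym[["Y_biomass"]] * 100 * MW_HEXOSE / params_ref$biomass_carbon_content
  e <- 100 * ym[["Y_ethanol"]]
  g <- 100 * ym[["Y_glycerol"]]
  r <- (params_ref$n_nadh * x - g) / 2
  if (r < 0)
    stop_infeasible("NADH", "engineered yields imply negative Rubisco flux")
  f <- (e - 2 * r) / 2
  if (f < 0)
    stop_infeasible("carbon", "Rubisco route alone exceeds the ethanol yield")
  o <- params_ref$n_nadph * x / 2
  p <- unclass(params_ref)
  p$n_co2_biomass <- 6 * (100 - f - g / 2 - o / 6 - (5 / 6) * r) / x - 1
  ac <- p$atp_coeffs
  atp_prod <- ac$ferment * f + ac$glycerol * g +
    (ac$rubisco + ac$nonoxppp_ru5p) * r +
    (ac$oxppp_hexose - ac$nonoxppp_ru5p) * o
  if (atp_prod <= 0)
    stop_input("engineered yields imply non-positive catabolic ATP formation")
  p$y_atp <- x / atp_prod
  p$gamma_biomass <- 4 * (1 + p$n_co2_biomass) - 2 * p$n_nadh + 2 * p$n_nadph
  list(params = validate_stoich_params(structure(p, class = "stoich_params")),
       capacity = r)
}

#' Generate synthetic chemostat steady-state records
#'
#' The condition's yields are first reproduced by an exactly balanced flux
#' distribution (see [chemostat_fixture()]); the replicate records are then
#' synthesised so that the analysis pipeline inverts the construction: broth
#' ethanol is the production-equivalent concentration reduced by the
#' steady-state evaporation factor `D / (D + k_evap)`, and the off-gas CO2
#' fraction follows from the net CO2 evolution rate, the gas flow and the
#' molar volume. Measurement noise is multiplicative Gaussian (truncated at
#' zero) with relative standard deviation `noise_sd`, drawn from a distinct
#' sub-stream per replicate.
#'
#' @param config a `generator_config` (see [chemostat_fixture()]).
#' @param noise_sd,replicates,seed overrides of the config values.
#' @return a `chemostat_records` data frame.
#' @export
generate_chemostat <- function(config, noise_sd = NULL, replicates = NULL,
                               seed = NULL) {
  noise_sd <- noise_sd %||% config$noise_sd %||% 0.01
  replicates <- replicates %||% config$replicates %||% 2
  seed <- seed %||% config$seed %||% 1
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (replicates < 1) stop_input("replicates must be >= 1")

  cp <- condition_params(config)
  params <- cp$params
  y <- predict_yields(cp$flux, params)
  D <- config$dilution_rate
  consumed_g <- (config$glucose_in - config$residual_glucose) +
    (config$galactose_in - config$residual_galactose)
  consumed_mol <- consumed_g / MW_HEXOSE
  biomass <- y$Y_biomass * consumed_g
  ethanol_broth <- y$Y_ethanol * consumed_mol * MW_ETHANOL *
    D / (D + params$k_evap)
  glycerol <- y$Y_glycerol * consumed_mol * MW_GLYCEROL
  co2_evo <- D * consumed_mol * cp$flux$co2_net / cp$flux$basis_mmol_hexose
  co2_out <- config$co2_in + co2_evo * molar_volume() / config$gas_flow

  rows <- lapply(seq_len(replicates), function(i) {
    set.seed(seed + i)
    jitter <- function(v) pmax(0, v * (1 + stats::rnorm(length(v), 0, noise_sd)))
    data.frame(replicate_id = i, dilution_rate = D,
               glucose_in = config$glucose_in,
               galactose_in = config$galactose_in,
               glucose_res = jitter(config$residual_glucose),
               galactose_res = jitter(config$residual_galactose),
               biomass = jitter(biomass), ethanol = jitter(ethanol_broth),
               glycerol = jitter(glycerol), gas_flow = config$gas_flow,
               co2_in = config$co2_in, co2_out = min(1, jitter(co2_out)))
  })
  as_chemostat_records(do.call(rbind, rows))
}

#' Generate synthetic batch fermentation time series
#'
#' Growth-coupled kinetics: constant biomass during the lag phase, then
#' exponential growth at `mu_max` with sugar consumption and product
#' formation proportional to growth (fixed yields) until sugar exhaustion.
#' Broth ethanol additionally decays first-order with `k_evap` during the
#' integration (explicit stepping, step <= 0.1 h). Noise as in
#' [generate_chemostat()].
#'
#' @param config a `generator_config` (see [batch_fixture()]).
#' @param noise_sd,replicates,seed overrides of the config values.
#' @return a `batch_series` data frame.
#' @export
generate_batch <- function(config, noise_sd = NULL, replicates = NULL,
                           seed = NULL) {
  noise_sd <- noise_sd %||% config$noise_sd %||% 0.01
  replicates <- replicates %||% config$replicates %||% 2
  seed <- seed %||% config$seed %||% 1
  if (config$inoculum <= 0) stop_domain("inoculum must be > 0")
  params <- config$params %||% stoich_params()
  k <- params$k_evap
  dt <- min(config$step %||% 0.02, 0.1)
  sample_times <- seq(0, config$t_end, by = config$sample_interval %||% 1)

  traj <- simulate_batch_trajectory(
    X0 = config$inoculum, S0 = config$sugar_0, mu = config$mu_max,
    lag = config$lag, Yx = config$Y_biomass_mass, Ye = config$Y_ethanol,
    Yg = config$Y_glycerol, k_evap = k, dt = dt, sample_times = sample_times)

  rows <- lapply(seq_len(replicates), function(i) {
    set.seed(seed + i)
    jitter <- function(v) pmax(0, v * (1 + stats::rnorm(length(v), 0, noise_sd)))
    data.frame(replicate_id = i, time = traj$time,
               biomass = jitter(traj$biomass), sugar = jitter(traj$sugar),
               ethanol = jitter(traj$ethanol), glycerol = jitter(traj$glycerol))
  })
  as_batch_series(do.call(rbind, rows))
}

# Deterministic explicit integration of the growth-coupled batch model.
simulate_batch_trajectory <- function(X0, S0, mu, lag, Yx, Ye, Yg, k_evap,
                                      dt, sample_times) {
  t_end <- max(sample_times)
  grid <- sort(unique(c(seq(0, t_end, by = dt), sample_times, lag)))
  X <- S <- E <- G <- numeric(length(grid))
  X[1] <- X0; S[1] <- S0; E[1] <- 0; G[1] <- 0
  for (i in seq_along(grid)[-1]) {
    h <- grid[i] - grid[i - 1]
    x <- X[i - 1]; s <- S[i - 1]
    if (grid[i] <= lag + 1e-12 || s <= 0 || mu <= 0) {
      dX <- 0
    } else {
      dX <- x * (exp(mu * h) - 1)           # exact within-step growth
      dS_need <- dX / Yx
      if (dS_need > s) { dX <- s * Yx; dS_need <- s }  # exhaustion, partial step
      s <- s - dS_need
    }
    dmol <- (dX / Yx) / MW_HEXOSE            # mol hexose consumed this step
    if (dX == 0) dmol <- 0
    X[i] <- x + dX
    S[i] <- s
    E[i] <- E[i - 1] * exp(-k_evap * h) + Ye * dmol * MW_ETHANOL
    G[i] <- G[i - 1] + Yg * dmol * MW_GLYCEROL
  }
  idx <- match(sample_times, grid)
  data.frame(time = sample_times, biomass = X[idx], sugar = S[idx],
             ethanol = E[idx], glycerol = G[idx])
}

#' Simulate synthetic fermentation data from a fitted scenario model
#'
#' Wraps [generate_chemostat()] / [generate_batch()] with the fitted model's
#' calibrated parameters and scenario yields, using the package's default
#' operating settings (sugar-limited chemostat at D = 0.05 h^-1 on
#' 12.5 + 12.5 g l^-1 glucose/galactose; 20 g l^-1 galactose batch).
#'
#' @param object a [redox_model()].
#' @param nsim number of replicate cultures.
#' @param seed integer seed.
#' @param mode scenario to simulate.
#' @param type `"chemostat"` or `"batch"`.
#' @param noise_sd relative measurement noise (default 0.01).
#' @param ... overrides of the generator config entries (e.g. `mu_max`,
#'   `lag`, `co2_in`).
#' @return a `chemostat_records` or `batch_series` data frame.
#' @export
simulate.redox_model <- function(object, nsim = 2, seed = 1,
                                 mode = c("prk_rubisco", "reference"),
                                 type = c("chemostat", "batch"),
                                 noise_sd = 0.01, ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  y <- predict_yields(if (mode == "reference") object$reference
                      else object$engineered, object$params)
  ref_y <- predict_yields(object$reference, object$params)
  if (type == "chemostat") {
    config <- utils::modifyList(list(
      mode = mode, params = object$params,
      Y_biomass = y$Y_biomass, Y_ethanol = y$Y_ethanol,
      Y_glycerol = y$Y_glycerol, reference_yields = ref_y,
      dilution_rate = 0.05, glucose_in = 12.5, galactose_in = 12.5,
      residual_glucose = 0.1, residual_galactose = 0.1, gas_flow = 30,
      co2_in = 0), list(...))
    generate_chemostat(structure(config, class = "generator_config"),
                       noise_sd = noise_sd, replicates = nsim, seed = seed)
  } else {
    config <- utils::modifyList(list(
      params = object$params, mu_max = 0.13, lag = 2, sugar_0 = 20,
      inoculum = 0.15, t_end = 48, sample_interval = 1, step = 0.02,
      Y_biomass_mass = y$Y_biomass, Y_ethanol = y$Y_ethanol,
      Y_glycerol = y$Y_glycerol), list(...))
    generate_batch(structure(config, class = "generator_config"),
                   noise_sd = noise_sd, replicates = nsim, seed = seed)
  }
}

#' Write generated records as delimited text
#'
#' @param x a `chemostat_records` or `batch_series` data frame.
#' @param path output path (tab-separated, documented header).
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
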
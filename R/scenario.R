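#' Net stoichiometry of the PRK/Rubisco ethanol route
#'
#' One mmol of ribulose-5-phosphate is phosphorylated by phosphoribulokinase
#' (one ATP), carboxylated by Rubisco (one CO2 fixed), and the two resulting
#' 3-phosphoglycerate are fermented to ethanol (two pyruvate-kinase ATP, two
#' NADH oxidised at alcohol dehydrogenase, two CO2 released at pyruvate
#' decarboxylase).
#'
#' @param v_rubisco Ru5P carboxylation flux, mmol (non-negative).
#' @param atp_coeffs ATP coefficient list as in [stoich_params()]; only the
#'   `rubisco` entry (net ATP per Ru5P, default +1) is used.
#' @return named numeric vector with components `ethanol`, `nadh`,
#'   `co2_fixed`, `co2_emitted`, `co2_net` and `atp` (deltas per route run at
#'   `v_rubisco`; `nadh` is negative: net oxidation).
#' @export
rubisco_route_stoichiometry <- function(v_rubisco,
                                        atp_coeffs = stoich_params()$atp_coeffs) {
  if (!is.numeric(v_rubisco) || any(v_rubisco < 0))
    stop_domain("v_rubisco must be >= 0")
  c(ethanol = 2 * v_rubisco,
    nadh = -2 * v_rubisco,
    co2_fixed = 1 * v_rubisco,
    co2_emitted = 2 * v_rubisco,
    co2_net = 1 * v_rubisco,
    atp = atp_coeffs$rubisco * v_rubisco)
}

#' Split ribulose-5-phosphate supply between the oxidative and non-oxidative
#' pentose-phosphate pathway
#'
#' Ru5P is preferentially drawn from the oxidative PPP, whose NADPH output is
#' capped at the biosynthetic NADPH requirement; any remaining demand is met
#' from glycolytic intermediates via the non-oxidative rearrangements (5/6
#' hexose per Ru5P). With `recycle = TRUE` the oxidative branch instead always
#' runs at exactly half the NADPH demand — the transhydrogenase-type NADH to
#' NADPH conversion — and surplus Ru5P is returned to glycolysis as a signed
#' negative non-oxidative flux. This is how a glycerol-producing reference
#' scenario (no Rubisco sink for Ru5P) meets its NADPH requirement.
#'
#' @param ru5p_demand Ru5P required, mmol.
#' @param nadph_demand NADPH required in biosynthesis, mmol.
#' @param recycle logical; allow a signed Ru5P return flux so the NADPH
#'   balance closes exactly (reference-style operation).
#' @return named numeric vector `c(v_oxppp, v_nonoxppp)` in mmol.
#' @export
allocate_ru5p <- function(ru5p_demand, nadph_demand, recycle = FALSE) {
  if (ru5p_demand < 0 || nadph_demand < 0)
    stop_domain("ru5p_demand and nadph_demand must be >= 0")
  v_oxppp <- if (recycle) nadph_demand / 2 else min(ru5p_demand, nadph_demand / 2)
  c(v_oxppp = v_oxppp, v_nonoxppp = ru5p_demand - v_oxppp)
}

# Assemble a flux_distribution from the primary pathway fluxes; every derived
# quantity (outputs, CO2 bookkeeping, residuals) is recomputed from scratch so
# closure checks are independent of the solving path.
flux_distribution <- function(f, g, x, o, n, r, params, mode,
                              dilution_rate = NA_real_) {
  ac <- params$atp_coeffs
  b <- params$n_co2_biomass
  ethanol <- 2 * f + 2 * r
  glycerol <- g
  co2_emitted <- 2 * f + 2 * r + o + b * x
  co2_fixed <- r
  hexose_used <- f + g / 2 + o + (5 / 6) * n + x * (1 + b) / 6

  maint <- maintenance_per_cmol(params, dilution_rate)
  atp_prod <- ac$ferment * f + ac$glycerol * g + ac$rubisco * r +
    ac$oxppp_hexose * o + ac$nonoxppp_ru5p * n - maint * x
  residuals <- c(
    carbon = 6 * hexose_used -
      (2 * ethanol + 3 * glycerol + x + co2_emitted - co2_fixed),
    nadh = params$n_nadh * x - g - 2 * r,
    nadph = 2 * o - params$n_nadph * x,
    atp = if (params$y_atp > 0) x - params$y_atp * atp_prod else x,
    electron = 24 * hexose_used -
      (E_PER_ETHANOL * ethanol + E_PER_GLYCEROL * glycerol +
         params$gamma_biomass * x),
    normalization = hexose_used - 100)

  structure(list(
    fluxes = c(v_ferment = f, v_glycerol = g, v_oxppp = o, v_nonoxppp = n,
               v_rubisco = r, v_biomass = x),
    ethanol_out = ethanol, glycerol_out = glycerol,
    co2_emitted = co2_emitted, co2_fixed = co2_fixed,
    co2_net = co2_emitted - co2_fixed,
    atp_produced = atp_prod,
    residuals = residuals,
    mode = mode, basis_mmol_hexose = 100),
    class = "flux_distribution")
}

maintenance_per_cmol <- function(params, dilution_rate) {
  if (params$maintenance_atp == 0) return(0)
  if (!is.finite(dilution_rate) || dilution_rate <= 0)
    stop_input("maintenance_atp > 0 requires a positive dilution_rate")
  params$maintenance_atp * params$biomass_carbon_content / dilution_rate
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution (%s mode), per %g mmol hexose\n",
              x$mode, x$basis_mmol_hexose))
  fl <- x$fluxes
  cat(sprintf("  fermentation %.4g, glycerol %.4g, oxPPP %.4g, non-oxPPP %+.4g\n",
              fl["v_ferment"], fl["v_glycerol"], fl["v_oxppp"], fl["v_nonoxppp"]))
  cat(sprintf("  Rubisco %.4g, biomass %.4g Cmol\n",
              fl["v_rubisco"], fl["v_biomass"]))
  cat(sprintf("  ethanol %.5g, glycerol %.4g, net CO2 %.5g (fixed %.4g)\n",
              x$ethanol_out, x$glycerol_out, x$co2_net, x$co2_fixed))
  cat(sprintf("  max |balance residual| = %.2e\n", max(abs(x$residuals))))
  invisible(x)
}

#' Convert a flux distribution to a delimited-text table
#'
#' Column order is fixed and documented: flux names then derived outputs then
#' residuals, one value per column, a single data row.
#'
#' @param flux a `flux_distribution`.
#' @param path output file; tab-separated.
#' @return the written data.frame, invisibly.
#' @export
write_flux_distribution <- function(flux, path) {
  stopifnot(inherits(flux, "flux_distribution"))
  out <- data.frame(as.list(flux$fluxes),
                    ethanol_out = flux$ethanol_out,
                    glycerol_out = flux$glycerol_out,
                    co2_emitted = flux$co2_emitted,
                    co2_fixed = flux$co2_fixed,
                    co2_net = flux$co2_net,
                    as.list(stats::setNames(flux$residuals,
                                            paste0("resid_", names(flux$residuals)))),
                    mode = flux$mode, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Solve a fermentation scenario as an exact balanced flux distribution
#'
#' Builds the lumped anaerobic network (hexose fermentation, glycerol shunt,
#' oxidative/non-oxidative pentose-phosphate pathway, optional PRK/Rubisco
#' ethanol route, biomass formation) and solves the carbon, NADH, NADPH and
#' ATP balances exactly on a basis of 100 mmol combined hexose uptake.
#' Biomass is coupled to catabolic ATP via `v_biomass = y_atp * net ATP`; the
#' oxidative PPP runs at exactly half the biosynthetic NADPH demand so the
#' NADPH balance always closes; glycerol closes the NADH balance in the
#' reference scenario and is minimised subject to the Rubisco capacity in the
#' engineered scenario. All relations are linear within each min()-branch of
#' the Ru5P allocation rule, so each branch is solved directly with
#' [solve()] and feasibility (non-negative fluxes, capacity respected)
#' selects the branch.
#'
#' @param params a [stoich_params()] object.
#' @param mode `"reference"` (wild-type, glycerol-producing) or
#'   `"prk_rubisco"` (Calvin-cycle route available).
#' @param co2_dissolved dissolved CO2 in mM, or `"saturating"` (default).
#'   Only caps the attainable Rubisco flux via [co2_saturation_factor()].
#' @param rubisco_capacity maximum Rubisco flux in mmol Ru5P per 100 mmol
#'   hexose, or `"unlimited"` (default).
#' @param dilution_rate h^-1; only needed when `maintenance_atp > 0`.
#' @return a `flux_distribution` object.
#' @examples
#' solve_scenario(stoich_params(), "reference")
#' solve_scenario(stoich_params(), "prk_rubisco")
#' @export
solve_scenario <- function(params, mode = c("reference", "prk_rubisco"),
                           co2_dissolved = "saturating",
                           rubisco_capacity = "unlimited",
                           dilution_rate = 0.05) {
  stopifnot(inherits(params, "stoich_params"))
  mode <- match.arg(mode)
  if (identical(rubisco_capacity, "unlimited")) rubisco_capacity <- Inf
  if (!is.numeric(rubisco_capacity) || rubisco_capacity < 0)
    stop_domain("rubisco_capacity must be >= 0 or \"unlimited\"")
  sat <- co2_saturation_factor(co2_dissolved, params$K_co2)
  cap <- if (sat == 0) 0 else rubisco_capacity * sat

  p <- params
  b <- p$n_co2_biomass
  ac <- p$atp_coeffs
  maint <- maintenance_per_cmol(p, dilution_rate)
  # per-Cmol coefficients once the NADPH closure o = n_nadph x / 2 is applied
  carbon_x <- p$n_nadph / 12 + (1 + b) / 6     # hexose per Cmol (incl. oxPPP C)
  atp_x <- (ac$oxppp_hexose - ac$nonoxppp_ru5p) * p$n_nadph / 2 - maint

  solve_branch <- function(mode, r_fixed = NULL) {
    # unknown order: f, g, x, r (r dropped when fixed)
    if (mode == "reference") r_fixed <- 0
    free_r <- is.null(r_fixed)
    nvar <- if (free_r) 4 else 3
    A <- matrix(0, nvar, nvar)
    rhs <- numeric(nvar)
    # carbon: f + g/2 + carbon_x * x + (5/6) r = 100
    A[1, 1:3] <- c(1, 1 / 2, carbon_x); rhs[1] <- 100
    # NADH: n_nadh x - g - 2 r = 0
    A[2, 1:3] <- c(0, -1, p$n_nadh); rhs[2] <- 0
    if (free_r) { A[1, 4] <- 5 / 6; A[2, 4] <- -2 }
    else { rhs[1] <- rhs[1] - (5 / 6) * r_fixed; rhs[2] <- rhs[2] + 2 * r_fixed }
    # ATP coupling (or x = 0 in the zero-growth limit)
    if (p$y_atp > 0) {
      A[3, 1:3] <- c(p$y_atp * ac$ferment, p$y_atp * ac$glycerol,
                     p$y_atp * atp_x - 1)
      if (free_r) A[3, 4] <- p$y_atp * (ac$rubisco + ac$nonoxppp_ru5p)
      else rhs[3] <- -p$y_atp * (ac$rubisco + ac$nonoxppp_ru5p) * r_fixed
    } else {
      A[3, 3] <- 1; rhs[3] <- 0
    }
    if (free_r) { A[4, ] <- c(0, 1, 0, 0); rhs[4] <- 0 }  # g = 0
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop_infeasible("linear system", conditionMessage(e)))
    f <- sol[1]; g <- if (free_r) 0 else sol[2]  # g pinned exactly at 0
    x <- sol[3]
    r <- if (free_r) sol[4] else r_fixed
    list(f = f, g = g, x = x, r = r)
  }

  tol <- -1e-9
  if (mode == "reference") {
    s <- solve_branch("reference")
  } else {
    s <- solve_branch("prk_rubisco")          # glycerol-free branch
    if (!(s$r <= cap + 1e-12) || s$r < tol || s$f < tol || s$x < tol) {
      s <- solve_branch("prk_rubisco", r_fixed = min(cap, max(0, s$r)))
    }
  }
  check_nonneg <- c(v_ferment = s$f, v_glycerol = s$g, v_rubisco = s$r,
                    v_biomass = s$x)
  if (any(check_nonneg < tol)) {
    bad <- names(check_nonneg)[which.min(check_nonneg)]
    stop_infeasible(switch(bad, v_glycerol = "NADH", v_ferment = "carbon",
                           v_rubisco = "NADH", v_biomass = "ATP"),
                    sprintf("%s = %.4g < 0", bad, check_nonneg[bad]))
  }
  s[c("f", "g", "r", "x")] <- lapply(s[c("f", "g", "r", "x")], function(v) max(v, 0))
  alloc <- c(v_oxppp = p$n_nadph * s$x / 2,
             v_nonoxppp = s$r - p$n_nadph * s$x / 2)
  fd <- flux_distribution(s$f, s$g, s$x, alloc[["v_oxppp"]],
                          alloc[["v_nonoxppp"]], s$r, p, mode, dilution_rate)
  worst <- which.max(abs(fd$residuals[c("carbon", "nadh", "nadph", "atp")]))
  if (max(abs(fd$residuals[c("carbon", "nadh", "nadph", "atp")])) > 1e-9 * 100)
    stop_infeasible(names(worst))
  fd
}

#' Convert a solved flux distribution to yields in measurement units
#'
#' @param flux a `flux_distribution` (per 100 mmol hexose).
#' @param params a [stoich_params()] object (for the biomass carbon content).
#' @return a one-row [yield_set()]: `Y_biomass` in g biomass per g hexose,
#'   `Y_ethanol` and `Y_glycerol` in mol per mol hexose.
#' @export
predict_yields <- function(flux, params) {
  stopifnot(inherits(flux, "flux_distribution"), inherits(params, "stoich_params"))
  basis <- flux$basis_mmol_hexose
  yield_set(
    Y_biomass = flux$fluxes[["v_biomass"]] * params$biomass_carbon_content /
      (basis * MW_HEXOSE / 1000) / 1000,
    Y_ethanol = flux$ethanol_out / basis,
    Y_glycerol = flux$glycerol_out / basis,
    corrected = TRUE)
}
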
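#' Fit the redox-balance scenario model to reference-strain yields
#'
#' The central modelling interface. Calibrates the stoichiometric parameters
#' (via [calibrate_stoich()]) so that the reference scenario — excess
#' biosynthetic NADH reoxidised by glycerol formation — reproduces the
#' observed chemostat yields exactly, then solves the engineered scenario in
#' which a phosphoribulokinase/Rubisco route fixes CO2 onto
#' ribulose-5-phosphate and ferments the resulting 3-phosphoglycerate to
#' ethanol, reoxidising the same NADH without carbon loss to glycerol.
#'
#' @param reference_yields a [yield_set()] of observed reference-strain
#'   yields, or a data frame coercible to one.
#' @param params starting [stoich_params()] (priors for the non-identifiable
#'   coefficients and all physical constants).
#' @param co2_dissolved,rubisco_capacity engineered-scenario settings passed
#'   to [solve_scenario()]; defaults assume CO2 saturation and unlimited
#'   enzyme capacity (the theoretical upper scenario).
#' @return an object of class `redox_model` with components `params`
#'   (calibrated), `reference` and `engineered` (`flux_distribution`s),
#'   `reference_yields` (the fit targets) and `gain` (relative ethanol-yield
#'   increase of the engineered over the reference scenario).
#' @examples
#' fit <- redox_model(yield_set(0.083, 1.56, 0.14))
#' summary(fit)
#' coef(fit)
#' predict(fit, mode = "prk_rubisco")
#' @seealso [solve_scenario()], [scenario_gain()], [simulate.redox_model()]
#' @export
redox_model <- function(reference_yields, params = stoich_params(),
                        co2_dissolved = "saturating",
                        rubisco_capacity = "unlimited") {
  if (!inherits(reference_yields, "yield_set"))
    reference_yields <- yield_set(reference_yields$Y_biomass,
                                  reference_yields$Y_ethanol,
                                  reference_yields$Y_glycerol)
  cal <- calibrate_stoich(params, reference_yields)
  ref <- solve_scenario(cal, "reference")
  eng <- solve_scenario(cal, "prk_rubisco", co2_dissolved = co2_dissolved,
                        rubisco_capacity = rubisco_capacity)
  structure(list(
    params = cal,
    reference = ref,
    engineered = eng,
    reference_yields = reference_yields,
    co2_dissolved = co2_dissolved,
    rubisco_capacity = rubisco_capacity,
    gain = (eng$ethanol_out - ref$ethanol_out) / ref$ethanol_out,
    call = match.call()), class = "redox_model")
}

#' @export
print.redox_model <- function(x, ...) {
  cat("Redox-balance scenario model of anaerobic yeast fermentation\n\n")
  yr <- predict_yields(x$reference, x$params)
  ye <- predict_yields(x$engineered, x$params)
  cat(sprintf("  %-22s %10s %12s\n", "yield", "reference", "PRK/Rubisco"))
  cat(sprintf("  %-22s %10.3f %12.3f\n", "biomass (g g-1)",
              yr$Y_biomass, ye$Y_biomass))
  cat(sprintf("  %-22s %10.3f %12.3f\n", "ethanol (mol mol-1)",
              yr$Y_ethanol, ye$Y_ethanol))
  cat(sprintf("  %-22s %10.3f %12.3f\n", "glycerol (mol mol-1)",
              yr$Y_glycerol, ye$Y_glycerol))
  cat(sprintf("\n  ethanol-yield gain: %.1f%%\n", 100 * x$gain))
  invisible(x)
}

#' @export
coef.redox_model <- function(object, ...) {
  p <- object$params
  c(n_nadh = p$n_nadh, n_nadph = p$n_nadph, n_co2_biomass = p$n_co2_biomass,
    y_atp = p$y_atp, gamma_biomass = p$gamma_biomass)
}

#' @export
fitted.redox_model <- function(object, ...) {
  predict_yields(object$reference, object$params)
}

#' Calibration residuals: fitted minus target yields
#' @param object a `redox_model`.
#' @param ... unused.
#' @return named numeric vector of yield residuals (should be ~0: the
#'   calibration is an exact linear inversion).
#' @export
residuals.redox_model <- function(object, ...) {
  fit <- yield_means(fitted(object))
  tgt <- yield_means(object$reference_yields)
  fit - tgt
}

#' Predict yields or fluxes for a scenario of a fitted model
#'
#' @param object a `redox_model`.
#' @param mode `"reference"` or `"prk_rubisco"`.
#' @param co2_dissolved,rubisco_capacity scenario settings (defaults: the
#'   values the model was fitted with).
#' @param type `"yields"` (default) or `"fluxes"`.
#' @param ... unused.
#' @return a [yield_set()] or a `flux_distribution`.
#' @export
predict.redox_model <- function(object, mode = c("prk_rubisco", "reference"),
                                co2_dissolved = NULL, rubisco_capacity = NULL,
                                type = c("yields", "fluxes"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  fd <- solve_scenario(object$params, mode,
                       co2_dissolved = co2_dissolved %||% object$co2_dissolved,
                       rubisco_capacity = rubisco_capacity %||% object$rubisco_capacity)
  if (type == "fluxes") fd else predict_yields(fd, object$params)
}

#' @export
summary.redox_model <- function(object, ...) {
  structure(list(model = object,
                 coef = coef(object),
                 residuals = residuals(object),
                 glycerol_reduction =
                   1 - object$engineered$glycerol_out /
                   max(object$reference$glycerol_out, .Machine$double.eps)),
            class = "summary.redox_model")
}

#' @export
print.summary.redox_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  glycerol reduction: %.0f%%\n", 100 * x$glycerol_reduction))
  cat("\nCalibrated coefficients (per Cmol biomass):\n")
  print(round(x$coef, 4))
  cat(sprintf("\nmax |calibration residual| = %.2e\n", max(abs(x$residuals))))
  cat(sprintf("max |balance residual| = %.2e per 100 mmol hexose\n",
              max(abs(c(x$model$reference$residuals,
                        x$model$engineered$residuals)))))
  invisible(x)
}

#' Sweep glycerol and ethanol yields against Rubisco capacity
#'
#' @param x a `redox_model`.
#' @param capacities Rubisco capacities to sweep (mmol Ru5P per 100 mmol
#'   hexose).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the sweep data frame.
#' @export
plot.redox_model <- function(x, capacities = seq(0, 1.2 *
                               x$engineered$fluxes[["v_rubisco"]],
                               length.out = 25), ...) {
  sweep <- vapply(capacities, function(cap) {
    y <- predict_yields(solve_scenario(x$params, "prk_rubisco",
                                       rubisco_capacity = cap), x$params)
    c(y$Y_ethanol, y$Y_glycerol)
  }, numeric(2))
  graphics::matplot(capacities, t(sweep), type = "l", lty = 1:2,
                    xlab = "Rubisco capacity (mmol Ru5P / 100 mmol hexose)",
                    ylab = "yield (mol mol-1)", ...)
  graphics::legend("right", legend = c("ethanol", "glycerol"), lty = 1:2,
                   col = 1:2, bty = "n")
  invisible(data.frame(capacity = capacities, Y_ethanol = sweep[1, ],
                       Y_glycerol = sweep[2, ]))
}

#' Relative ethanol-yield gain of the engineered over the reference scenario
#'
#' Fraction by which the molar ethanol yield increases when the PRK/Rubisco
#' route (at CO2 saturation and unlimited capacity) replaces glycerol
#' formation as the sink for excess biosynthetic NADH.
#'
#' @param params calibrated [stoich_params()].
#' @return relative gain as a fraction (0.10 means +10 percent).
#' @export
scenario_gain <- function(params) {
  ref <- solve_scenario(params, "reference")
  eng <- solve_scenario(params, "prk_rubisco")
  (eng$ethanol_out - ref$ethanol_out) / ref$ethanol_out
}

#' Project the global ethanol-production gain from eliminating glycerol
#'
#' If a fraction `f` of the consumed sugar is currently lost to glycerol and
#' that sugar were instead converted to ethanol at the prevailing yield, total
#' production `V` (made from the remaining `1 - f` of the sugar) would rise by
#' `V * f / (1 - f)`.
#'
#' @param total_volume current production volume (any unit, e.g. billion
#'   litres per year).
#' @param sugar_loss_fraction fraction of consumed sugar lost to the
#'   by-product, in `[0, 1)`.
#' @return list with `additional` (raw) and `additional_rounded` (one
#'   significant figure, the headline convention).
#' @examples
#' project_global_gain(110, 0.04)  # ~4.6, headline 5
#' @export
project_global_gain <- function(total_volume, sugar_loss_fraction) {
  if (total_volume <= 0) stop_domain("total_volume must be > 0")
  if (sugar_loss_fraction < 0 || sugar_loss_fraction >= 1)
    stop_domain("sugar_loss_fraction must lie in [0, 1)")
  add <- total_volume * sugar_loss_fraction / (1 - sugar_loss_fraction)
  list(additional = add, additional_rounded = signif1(add))
}
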
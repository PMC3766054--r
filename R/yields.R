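#' Yield sets: biomass and product yields with replicate spread
#'
#' A `yield_set` is a data frame with one row per replicate culture and
#' columns `Y_biomass` (g biomass per g sugar), `Y_ethanol` and `Y_glycerol`
#' (mol per mol hexose), plus a `replicate` id. The attribute `corrected`
#' records whether the ethanol evaporation correction was applied.
#'
#' @param Y_biomass,Y_ethanol,Y_glycerol numeric vectors (recycled to the
#'   longest).
#' @param replicate replicate identifiers.
#' @param corrected logical flag: ethanol values are evaporation-corrected.
#' @return an object of classes `yield_set` and `data.frame`.
#' @export
yield_set <- function(Y_biomass, Y_ethanol, Y_glycerol,
                      replicate = seq_along(Y_ethanol), corrected = FALSE) {
  d <- data.frame(replicate = replicate, Y_biomass = Y_biomass,
                  Y_ethanol = Y_ethanol, Y_glycerol = Y_glycerol)
  if (any(d$Y_biomass < 0) || any(d$Y_ethanol < 0) || any(d$Y_glycerol < 0))
    stop_input("yields must be >= 0")
  if (any(d$Y_ethanol > 2) || any(d$Y_glycerol > 2))
    stop_input("molar yields on hexose cannot exceed 2")
  structure(d, corrected = corrected, class = c("yield_set", "data.frame"))
}

#' Mean absolute deviation from the mean
#'
#' Replicate spread is reported as "average +/- mean deviation" (not standard
#' deviation), matching common duplicate-culture reporting.
#'
#' @param x numeric vector.
#' @return mean of `|x - mean(x)|`.
#' @export
mean_deviation <- function(x) mean(abs(x - mean(x)))

#' @export
summary.yield_set <- function(object, ...) {
  cols <- c("Y_biomass", "Y_ethanol", "Y_glycerol")
  out <- data.frame(
    yield = cols,
    mean = vapply(object[cols], mean, numeric(1)),
    mean_deviation = vapply(object[cols], mean_deviation, numeric(1)),
    n = nrow(object), row.names = NULL)
  structure(out, corrected = attr(object, "corrected"),
            class = c("summary.yield_set", "data.frame"))
}

#' @export
print.summary.yield_set <- function(x, digits = 3, ...) {
  cat("Yields (average +/- mean deviation, n =", x$n[1], "replicates",
      if (isTRUE(attr(x, "corrected"))) "- evaporation-corrected", ")\n")
  units <- c(Y_biomass = "g g-1", Y_ethanol = "mol mol-1",
             Y_glycerol = "mol mol-1")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s %.*g +/- %.2g %s\n", x$yield[i], digits, x$mean[i],
                x$mean_deviation[i], units[[x$yield[i]]]))
  invisible(x)
}

yield_means <- function(y) {
  vapply(y[c("Y_biomass", "Y_ethanol", "Y_glycerol")], mean, numeric(1))
}
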
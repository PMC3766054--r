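#' Maximum specific growth rate and lag time from a batch growth curve
#'
#' Fits `ln(biomass) ~ time` by least squares over the longest contiguous
#' window of at least `min_points` positive-biomass samples whose fit attains
#' R^2 >= `r2_min` (ties broken by higher R^2); plateau windows (constant
#' biomass) are not candidates. The slope is mu_max; the lag
#' time is the back-extrapolation of the fitted line to the inoculum level:
#' `lag = (ln(X_0) - intercept) / mu_max` with `X_0` the first biomass
#' sample. A series with no net growth at all returns mu_max = 0 with an
#' undefined lag.
#'
#' @param series a `batch_series` data frame holding one replicate (or
#'   vectors via `time`/`biomass`).
#' @param time,biomass alternative direct interface.
#' @param r2_min window acceptance threshold (default 0.999; at looser
#'   thresholds the maximal window absorbs lag and stationary samples and
#'   biases mu_max low).
#' @param min_points minimum window size (default 4).
#' @return list of class `growth_fit`: `mu_max` (h^-1), `lag_time` (h, `NA`
#'   when mu_max = 0), `window` (start and end times), `r_squared`,
#'   `n_points`.
#' @export
fit_growth_rate <- function(series = NULL, time = series$time,
                            biomass = series$biomass, r2_min = 0.999,
                            min_points = 4) {
  if (!is.null(series)) {
    series <- as.data.frame(series)
    if (length(unique(series$replicate_id %||% 1)) > 1)
      stop_input("fit_growth_rate expects a single replicate")
  }
  keep <- biomass > 0
  time <- time[keep]; biomass <- biomass[keep]
  n <- length(time)
  if (n < min_points)
    stop_input(sprintf("need >= %d positive-biomass samples", min_points))
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  ly <- log(biomass)

  if (max(ly) - min(ly) < 1e-9)                 # no net growth at all
    return(structure(list(mu_max = 0, lag_time = NA_real_,
                          window = c(start = time[1], end = time[n]),
                          r_squared = 1, n_points = n),
                     class = "growth_fit"))

  window_fit <- function(i, j) {
    t_w <- time[i:j]; y_w <- ly[i:j]
    if (max(y_w) - min(y_w) < 1e-9) return(NULL)  # lag/stationary plateau
    fit <- stats::lm.fit(cbind(1, t_w), y_w)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y_w - mean(y_w))^2)
    list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
         r2 = 1 - ss_res / ss_tot)
  }

  best <- NULL
  for (len in seq(n, min_points)) {
    for (i in seq_len(n - len + 1)) {
      w <- window_fit(i, i + len - 1)
      if (!is.null(w) && w$slope > 0 && w$r2 >= r2_min &&
          (is.null(best) || len > best$len ||
           (len == best$len && w$r2 > best$r2))) {
        best <- c(w, list(i = i, j = i + len - 1, len = len))
      }
    }
    if (!is.null(best)) break  # maximal window length found
  }
  if (is.null(best))
    stop(errorCondition(
      sprintf("no window of >= %d samples reaches R^2 >= %g", min_points, r2_min),
      class = c("redoxferm_fit_error", "error")))
  mu <- max(best$slope, 0)
  lag <- if (mu > 0) (ly[1] - best$intercept) / best$slope else NA_real_
  structure(list(mu_max = mu, lag_time = unname(lag),
                 window = c(start = time[best$i], end = time[best$j]),
                 r_squared = unname(best$r2), n_points = best$len),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("mu_max = %.4g h^-1, lag = %.3g h (window %g-%g h, R^2 = %.4f, n = %d)\n",
              x$mu_max, x$lag_time, x$window["start"], x$window["end"],
              x$r_squared, x$n_points))
  invisible(x)
}
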
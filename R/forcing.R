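# Time-dependent boundary conditions: temperatures, inflow fugacities and
# direct emissions. Series are piecewise linear in time (days); temperature
# slopes are taken from the segment slopes exactly, never by numerical
# differentiation.

.as_series <- function(x, field) {
  if (is.numeric(x) && length(x) == 1) {
    return(list(time = c(0, 1), value = c(x, x)))
  }
  x <- as.data.frame(x)
  .check(all(c("time", "value") %in% names(x)), field,
         "a series needs `time` and `value` columns", "forcing")
  .check(nrow(x) >= 2 && all(diff(x$time) > 0), field,
         "time grid must be strictly increasing", "forcing")
  list(time = as.numeric(x$time), value = as.numeric(x$value))
}

#' Forcing time series
#'
#' @param air_temp,water_temp Temperatures in kelvin: either a single number
#'   (constant) or a data frame with columns `time` (days) and `value`,
#'   interpolated piecewise linearly and held constant outside the grid.
#' @param inflow_fug_air,inflow_fug_water Fugacities (Pa) of advective
#'   inflows; constant or series as above.
#' @param emission Named numeric vector of direct emissions (mol day^-1) into
#'   compartments, e.g. `c(water = 0.5)`.
#' @return An object of class `fug_forcing`.
#' @export
fug_forcing <- function(air_temp, water_temp, inflow_fug_air = 0,
                        inflow_fug_water = 0, emission = c(water = 0)) {
  out <- list(
    air_temp = .as_series(air_temp, "air_temp"),
    water_temp = .as_series(water_temp, "water_temp"),
    inflow_fug_air = .as_series(inflow_fug_air, "inflow_fug_air"),
    inflow_fug_water = .as_series(inflow_fug_water, "inflow_fug_water"),
    emission = emission
  )
  .check(all(out$air_temp$value > 0) && all(out$water_temp$value > 0),
         "temperature", "temperatures must be positive kelvin", "forcing")
  .check(all(out$inflow_fug_air$value >= 0) &&
           all(out$inflow_fug_water$value >= 0),
         "inflow fugacity", "must be >= 0", "forcing")
  .check(is.numeric(emission) && all(emission >= 0) &&
           (length(emission) == 0 || !is.null(names(emission))),
         "emission", "must be a named nonnegative numeric vector", "forcing")
  structure(out, class = "fug_forcing")
}

# value and exact slope of a piecewise-linear series at time t (scalar)
.series_at <- function(s, t) {
  k <- length(s$time)
  i <- findInterval(t, s$time, rightmost.closed = TRUE)
  if (i < 1) {
    return(c(value = s$value[1], slope = 0))
  }
  if (i >= k) {
    return(c(value = s$value[k], slope = 0))
  }
  slope <- (s$value[i + 1] - s$value[i]) / (s$time[i + 1] - s$time[i])
  c(value = s$value[i] + slope * (t - s$time[i]), slope = slope)
}

#' Evaluate the forcing at a time point
#'
#' @param forcing A [fug_forcing()].
#' @param t Time (days).
#' @return A list with `temp_air`, `temp_water` (K), their exact
#'   piecewise-linear slopes `dtemp_air_dt`, `dtemp_water_dt` (K day^-1),
#'   `inflow_fug_air`, `inflow_fug_water` (Pa) and the `emission` vector.
#' @export
forcing_at <- function(forcing, t) {
  stopifnot(inherits(forcing, "fug_forcing"))
  ta <- .series_at(forcing$air_temp, t)
  tw <- .series_at(forcing$water_temp, t)
  list(
    temp_air = ta[["value"]], dtemp_air_dt = ta[["slope"]],
    temp_water = tw[["value"]], dtemp_water_dt = tw[["slope"]],
    inflow_fug_air = .series_at(forcing$inflow_fug_air, t)[["value"]],
    inflow_fug_water = .series_at(forcing$inflow_fug_water, t)[["value"]],
    emission = forcing$emission
  )
}
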
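#' Saturation vapour pressure of air over liquid water
#'
#' Magnus/Tetens form `e_s(t) = 0.6108 * exp(17.27 t / (t + 237.3))` kPa,
#' the standard choice in dead-fuel-moisture work. The formula sits behind
#' this single function so an alternative curve can be swapped in.
#'
#' @param t air temperature in degrees Celsius; must lie in the physical
#'   range -90..60.
#' @return saturation vapour pressure in kPa; strictly increasing in `t`.
#' @examples
#' saturation_vapour_pressure(20) # 2.338 kPa
#' @export
saturation_vapour_pressure <- function(t) {
  if (any(!is.finite(t)) || any(t < -90 | t > 60))
    stop("air temperature outside the physical range -90..60 degC")
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Vapour pressure deficit from temperature and dew point
#'
#' `VPD = e_s(t) - e_s(t_d)`: the gap between the air's water-holding
#' capacity at its temperature and the actual vapour pressure implied by the
#' dew point. Zero exactly at saturation (`t_d == t`).
#'
#' @param t air temperature, degC.
#' @param t_d dew point temperature, degC; must not exceed `t`
#'   (supersaturation is rejected).
#' @return VPD in kPa, non-negative.
#' @export
vpd_from_dewpoint <- function(t, t_d) {
  if (any(t_d > t))
    stop("dew point exceeds air temperature (supersaturation): ",
         sum(t_d > t), " value(s)")
  saturation_vapour_pressure(t) - saturation_vapour_pressure(t_d)
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' `VPD = e_s(t) * (1 - rh/100)`, the variant used for 3-hourly GCM output
#' where dew point is not archived. Relative humidity marginally above 100%
#' (input rounding) is clamped to saturation with a count reported via a
#' warning; values above 100.5% are a hard error.
#'
#' @param t air temperature, degC.
#' @param rh relative humidity, percent, in 0..100 (tolerance to 100.5).
#' @return VPD in kPa, non-negative.
#' @export
vpd_from_rh <- function(t, rh) {
  if (any(rh < 0 | rh > 100.5))
    stop("relative humidity outside 0..100%")
  over <- rh > 100
  if (any(over)) {
    warning(sum(over), " rh value(s) marginally above 100% clamped to saturation")
    rh[over] <- 100
  }
  saturation_vapour_pressure(t) * (1 - rh / 100)
}

#' Daily maximum VPD at the time of daily maximum temperature
#'
#' For every cell-day, locates the sub-daily step at which air temperature is
#' maximal (earliest step wins on ties) and computes VPD from the temperature
#' and humidity *at that step*. This is deliberately not the day's maximum
#' pointwise VPD: the convention follows daily fire-danger practice, pairing
#' the day's peak temperature with the coincident humidity.
#'
#' @param t_subdaily [climate_grid()] of air temperature; units `"degC"` or
#'   `"K"` (Kelvin is converted internally).
#' @param humidity_subdaily [climate_grid()] on the same axes; dew point
#'   (degC/K) or relative humidity (%) according to `humidity_kind`.
#' @param humidity_kind `"dewpoint"` or `"rh"`.
#' @return a daily [climate_grid()] of VPD in kPa (one step per day).
#' @export
daily_max_vpd <- function(t_subdaily, humidity_subdaily,
                          humidity_kind = c("dewpoint", "rh")) {
  humidity_kind <- match.arg(humidity_kind)
  if (!same_axes(t_subdaily, humidity_subdaily))
    stop("temperature and humidity grids have mismatched axes")
  tv <- to_degC(t_subdaily$values, t_subdaily$units, "temperature")
  hv <- humidity_subdaily$values
  if (humidity_kind == "dewpoint") {
    hv <- to_degC(hv, humidity_subdaily$units, "dew point")
  } else if (!identical(humidity_subdaily$units, "%")) {
    stop("relative humidity grid must have units \"%\"")
  }
  d <- dim(tv)
  spd <- t_subdaily$steps_per_day
  nd <- d[3L] %/% spd
  ncell <- d[1L] * d[2L]
  # (cell, day, step) layout so argmax over steps is a row-wise max.col
  tm <- matrix(aperm(array(tv, c(ncell, spd, nd)), c(1L, 3L, 2L)),
               ncell * nd, spd)
  if (any(!is.finite(tm)))
    stop("missing temperature values: cannot locate the daily maximum")
  hm <- matrix(aperm(array(hv, c(ncell, spd, nd)), c(1L, 3L, 2L)),
               ncell * nd, spd)
  pick <- max.col(tm, ties.method = "first")
  sel <- cbind(seq_len(nrow(tm)), pick)
  t_at <- tm[sel]
  h_at <- hm[sel]
  vpd <- if (humidity_kind == "dewpoint") vpd_from_dewpoint(t_at, h_at)
         else vpd_from_rh(t_at, h_at)
  climate_grid(array(vpd, c(d[1L], d[2L], nd)), var = "vpd", units = "kPa",
               years = t_subdaily$years, steps_per_day = 1L,
               lat = t_subdaily$lat, lon = t_subdaily$lon)
}

to_degC <- function(x, units, what) {
  if (identical(units, "degC")) return(x)
  if (identical(units, "K")) return(x - 273.15)
  stop(sprintf("%s units must be degC or K, got %s", what, units))
}
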
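#' Specification of a synthetic world
#'
#' Collects the grid size, calendar and master seed from which every
#' synthetic dataset is generated. All generators are fully deterministic
#' given the spec: the same spec yields bit-identical output.
#'
#' @param n_lat,n_lon number of grid cells in each direction (>= 1).
#' @param years consecutive calendar years to simulate.
#' @param steps_per_day sub-daily steps (24 emulates hourly reanalysis,
#'   8 emulates 3-hourly GCM output); must divide 24.
#' @param seed integer master seed.
#' @return an object of class `"world_spec"`.
#' @export
world_spec <- function(n_lat, n_lon, years, steps_per_day = 24L, seed = 1L) {
  if (n_lat < 1L || n_lon < 1L) stop("grid must have at least one cell")
  if (length(years) < 1L || any(diff(years) != 1L))
    stop("`years` must be non-empty consecutive calendar years")
  if (24L %% steps_per_day != 0L) stop("`steps_per_day` must divide 24")
  structure(list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
                 years = as.integer(years),
                 steps_per_day = as.integer(steps_per_day),
                 seed = as.integer(seed)),
            class = "world_spec")
}

#' Planted logistic fire-occurrence law
#'
#' The "true" relationship between daily maximum VPD and the probability of
#' fire used by the generator: `P(fire | v) = plogis(beta0 + beta1 * v)`.
#' Data generated under a planted law let the model-fitting stage be
#' validated by parameter recovery; the planted 50% threshold is
#' `-beta0 / beta1`.
#'
#' @param beta0 logit intercept (dimensionless).
#' @param beta1 logit slope per kPa; must be > 0 so the threshold is unique.
#' @return an object of class `"fire_law"`.
#' @export
fire_law <- function(beta0, beta1) {
  if (!is.finite(beta1) || beta1 <= 0)
    stop("`beta1` must be positive: fire probability must increase with VPD")
  structure(list(beta0 = beta0, beta1 = beta1,
                 threshold = -beta0 / beta1), class = "fire_law")
}

# run `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# stationary AR(1) path with marginal SD `sd` and lag-1 correlation `rho`
ar1_path <- function(n, rho, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  if (rho == 0) return(stats::rnorm(n, sd = sd))
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
  innov[1L] <- stats::rnorm(1L, sd = sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Simulate paired temperature and dew point fields
#'
#' Air temperature is the sum of a sinusoidal annual cycle, a sinusoidal
#' diurnal cycle peaking at 14:00, a shared regional AR(1) day-scale
#' anomaly (spatial coherence), and an independent per-cell AR(1) noise
#' path. Dew point is temperature minus a non-negative dew point
#' depression (its own seasonal cycle plus AR(1) noise, floored at zero),
#' so `dewpoint <= temperature` holds at every cell and step by
#' construction.
#'
#' @param spec a [world_spec()].
#' @param t_mean annual-mean temperature, degC.
#' @param t_seasonal amplitude of the annual cycle, degC.
#' @param t_diurnal peak-to-trough amplitude of the diurnal cycle, degC.
#' @param ar1 lag-1 autocorrelation of the per-cell noise (on sub-daily
#'   steps) and of the regional anomaly (on days).
#' @param noise_sd marginal SD of the per-cell noise, degC.
#' @param regional_sd marginal SD of the shared regional anomaly, degC.
#' @param dep_mean mean dew point depression, degC.
#' @param dep_seasonal amplitude of the depression's annual cycle, degC
#'   (drier air in the warm season).
#' @param dep_sd marginal SD of the depression noise, degC; 0 gives a
#'   deterministic depression.
#' @return list with elements `temperature` and `dewpoint`, both
#'   [climate_grid()]s in degC on identical axes.
#' @export
simulate_climate <- function(spec, t_mean = 15, t_seasonal = 10,
                             t_diurnal = 8, ar1 = 0.7, noise_sd = 2,
                             regional_sd = 1.5, dep_mean = 6,
                             dep_seasonal = 3, dep_sd = 2.5) {
  stopifnot(inherits(spec, "world_spec"))
  nd <- 365L * length(spec$years)
  spd <- spec$steps_per_day
  nt <- nd * spd
  doy <- rep(rep(1:365, length(spec$years)), each = spd)
  hour <- rep(seq(0, 24 - 24 / spd, by = 24 / spd), nd)
  seasonal <- t_seasonal * cos(2 * pi * (doy - 196) / 365)
  diurnal <- (t_diurnal / 2) * cos(2 * pi * (hour - 14) / 24)
  dep_cycle <- pmax(dep_mean + dep_seasonal * cos(2 * pi * (doy - 196) / 365), 0)
  with_seed(spec$seed, {
    regional <- rep(ar1_path(nd, ar1, regional_sd), each = spd)
    tarr <- array(NA_real_, c(spec$n_lat, spec$n_lon, nt))
    darr <- array(NA_real_, c(spec$n_lat, spec$n_lon, nt))
    for (i in seq_len(spec$n_lat)) for (j in seq_len(spec$n_lon)) {
      temp <- t_mean + seasonal + diurnal + regional + ar1_path(nt, ar1, noise_sd)
      depression <- pmax(dep_cycle + ar1_path(nt, ar1, dep_sd), 0)
      tarr[i, j, ] <- temp
      darr[i, j, ] <- temp - depression
    }
    list(
      temperature = climate_grid(tarr, "tas", "degC", spec$years, spd),
      dewpoint = climate_grid(darr, "dewpoint", "degC", spec$years, spd))
  })
}

#' Simulate a daily VPD field with a known Gaussian AR(1) marginal
#'
#' A direct generator of daily maximum VPD whose per-cell marginal
#' distribution is Normal(`mean`, `sd`) (clamped at zero, which leaves
#' exceedance probabilities of positive thresholds unchanged). Used
#' wherever a closed-form exceedance probability
#' `P(VPD > theta) = 1 - pnorm((theta - mean)/sd)` is needed as an oracle.
#'
#' @param spec a [world_spec()]; its `steps_per_day` is ignored (output is
#'   daily).
#' @param mean,sd marginal mean and SD of daily VPD, kPa.
#' @param ar1 lag-1 day-to-day autocorrelation.
#' @return a daily VPD [climate_grid()] in kPa.
#' @export
simulate_vpd_grid <- function(spec, mean = 2, sd = 0.5, ar1 = 0) {
  stopifnot(inherits(spec, "world_spec"))
  nd <- 365L * length(spec$years)
  with_seed(spec$seed, {
    arr <- array(NA_real_, c(spec$n_lat, spec$n_lon, nd))
    for (i in seq_len(spec$n_lat)) for (j in seq_len(spec$n_lon))
      arr[i, j, ] <- pmax(mean + ar1_path(nd, ar1, sd), 0)
    climate_grid(arr, "vpd", "kPa", spec$years, 1L)
  })
}

#' Simulate burned-area records under a planted fire law
#'
#' Each cell-day burns independently with probability
#' `plogis(beta0 + beta1 * VPD)`. Burned cell-days are recorded as one
#' event row each. A historical burn table covering the `history_years`
#' before the study period can also be emitted (independent of the law,
#' uniform per cell-day at `history_rate`) to exercise the five-year
#' burn-exclusion filter with counts that are exact by construction.
#'
#' @param vpd_daily daily VPD [climate_grid()] in kPa.
#' @param law a [fire_law()].
#' @param seed integer seed for the burn draws.
#' @param stratum_map optional character matrix `(n_lat, n_lon)` assigning
#'   each cell to a stratum (`NA` = outside the study area); default one
#'   stratum `"S1"` everywhere.
#' @param history_years number of pre-period years for the historical table.
#' @param history_rate per cell-day burn probability in the pre-period.
#' @return a `data.frame` of class `"fire_events"` with columns
#'   `lat_idx, lon_idx, lat, lon, date` (day index), `year, stratum`, and a
#'   `"history"` attribute holding the pre-period table (same columns,
#'   `date <= 0`).
#' @export
simulate_fire_occurrence <- function(vpd_daily, law, seed = 1L,
                                     stratum_map = NULL,
                                     history_years = 0L, history_rate = 0) {
  stopifnot(inherits(law, "fire_law"))
  stopifnot_units(vpd_daily, "kPa", "VPD grid")
  if (vpd_daily$steps_per_day != 1L) stop("`vpd_daily` must be daily resolution")
  d <- dim(vpd_daily$values)
  if (is.null(stratum_map))
    stratum_map <- matrix("S1", d[1L], d[2L])
  p <- stats::plogis(law$beta0 + law$beta1 * vpd_daily$values)
  with_seed(seed, {
    burned <- array(stats::runif(length(p)) < p, dim = d)
    idx <- which(burned, arr.ind = TRUE)
    ev <- event_table(idx, vpd_daily, stratum_map)
    hist_ev <- NULL
    if (history_years > 0L && history_rate > 0) {
      nh <- 365L * history_years
      hburn <- array(stats::runif(d[1L] * d[2L] * nh) < history_rate,
                     c(d[1L], d[2L], nh))
      hidx <- which(hburn, arr.ind = TRUE)
      hist_ev <- event_table(hidx, vpd_daily, stratum_map)
      hist_ev$date <- hist_ev$date - nh  # day indices <= 0: pre-period
      hist_ev$year <- NA_integer_
    }
    attr(ev, "history") <- hist_ev
    ev
  })
}

event_table <- function(idx, grid, stratum_map) {
  ev <- data.frame(
    lat_idx = idx[, 1L], lon_idx = idx[, 2L],
    lat = grid$lat[idx[, 1L]], lon = grid$lon[idx[, 2L]],
    date = idx[, 3L],
    year = grid$years[(idx[, 3L] - 1L) %/% 365L + 1L],
    stratum = stratum_map[idx[, 1L:2L, drop = FALSE]])
  ev <- ev[!is.na(ev$stratum), , drop = FALSE]
  ev <- ev[order(ev$date, ev$lat_idx, ev$lon_idx), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("fire_events", "data.frame")
  ev
}

#' Simulate a biased GCM-like VPD series from a reference series
#'
#' The "model historical" series is an affine distortion of the reference
#' (scale then shift), emulating a climate model's distributional bias; the
#' "model future" series adds a constant `future_delta` on top. The planted
#' distortion parameters are returned so bias-correction recovery can be
#' asserted exactly.
#'
#' @param reference a daily VPD [climate_grid()] (kPa).
#' @param bias_shift additive bias, kPa.
#' @param bias_scale multiplicative bias, > 0.
#' @param future_delta climate-change shift added to the future series, kPa.
#' @return list with `historical` and `future` [climate_grid()]s and a
#'   `distortion` list recording the planted parameters.
#' @export
simulate_gcm_like <- function(reference, bias_shift = 0, bias_scale = 1,
                              future_delta = 0) {
  if (bias_scale <= 0) stop("`bias_scale` must be positive")
  stopifnot_units(reference, "kPa", "reference grid")
  hist_vals <- bias_scale * reference$values + bias_shift
  mk <- function(v) climate_grid(v, "vpd", "kPa", reference$years,
                                 reference$steps_per_day,
                                 lat = reference$lat, lon = reference$lon)
  list(historical = mk(hist_vals),
       future = mk(hist_vals + future_delta),
       distortion = list(bias_shift = bias_shift, bias_scale = bias_scale,
                         future_delta = future_delta))
}

#' Simulate a fine-resolution density raster (population or biomass)
#'
#' Log-normal positive values with a planted fraction of exactly-zero cells
#' (the missing-data convention of biomass products). The fine grid nests
#' within the climate grid an integer number of times (`refine` fine cells
#' per coarse cell along each axis).
#'
#' @param spec a [world_spec()] describing the coarse climate grid.
#' @param kind `"population"` or `"biomass"` (unit tag only).
#' @param zero_fraction expected fraction of exactly-zero cells, in [0, 1).
#' @param refine fine cells per coarse cell per axis (>= 1).
#' @param meanlog,sdlog log-normal parameters of the positive values.
#' @return a numeric matrix `(n_lat * refine, n_lon * refine)` with
#'   attributes `kind` and `refine`.
#' @export
simulate_density_raster <- function(spec, kind = c("population", "biomass"),
                                    zero_fraction = 0.1, refine = 4L,
                                    meanlog = 4, sdlog = 1) {
  kind <- match.arg(kind)
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("`zero_fraction` must be in [0, 1)")
  if (refine < 1L) stop("`refine` must be >= 1")
  nr <- spec$n_lat * refine
  nc <- spec$n_lon * refine
  with_seed(spec$seed + 7L, {
    v <- stats::rlnorm(nr * nc, meanlog, sdlog)
    v[stats::runif(nr * nc) < zero_fraction] <- 0
    structure(matrix(v, nr, nc), kind = kind, refine = as.integer(refine))
  })
}
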
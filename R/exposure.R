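#' Broadcast per-stratum thresholds onto the climate grid
#'
#' Paints each stratum's fitted VPD_P=50 onto the cells of that stratum;
#' cells outside every stratum stay `NA` (missing, not zero).
#'
#' @param stratum_map character matrix of stratum ids (`NA` outside the
#'   study area).
#' @param thresholds named numeric vector, kPa, one entry per stratum.
#' @return numeric matrix of per-cell thresholds.
#' @export
threshold_map <- function(stratum_map, thresholds) {
  missing_strata <- setdiff(stats::na.omit(unique(as.vector(stratum_map))),
                            names(thresholds))
  if (length(missing_strata))
    stop("no threshold supplied for strata: ",
         paste(missing_strata, collapse = ", "))
  out <- matrix(NA_real_, nrow(stratum_map), ncol(stratum_map))
  in_map <- !is.na(stratum_map)
  out[in_map] <- thresholds[stratum_map[in_map]]
  out
}

#' Mean annual frequency of threshold-exceedance days
#'
#' Counts, per cell, the days on which daily maximum VPD strictly exceeds
#' that cell's threshold, divided by the number of years — the "potential
#' fire days" climatology. Cells with no threshold (outside every
#' stratum) are missing, not zero.
#'
#' @param vpd_daily daily VPD [climate_grid()] (kPa).
#' @param thresholds per-cell threshold matrix from [threshold_map()], or
#'   a single number.
#' @param years optional subset of the grid's years to use (must be at
#'   least one full year).
#' @return an object of class `"exceedance_clim"`: a matrix of days/year
#'   with attributes `period` (years used) and `thresholds`.
#' @export
exceedance_days <- function(vpd_daily, thresholds, years = NULL) {
  stopifnot_units(vpd_daily, "kPa", "VPD grid")
  if (vpd_daily$steps_per_day != 1L) stop("`vpd_daily` must be daily")
  d <- dim(vpd_daily$values)
  if (length(thresholds) == 1L)
    thresholds <- matrix(thresholds, d[1L], d[2L])
  if (!identical(dim(thresholds), d[1:2]))
    stop("threshold matrix does not match the grid")
  if (is.null(years)) years <- vpd_daily$years
  if (length(years) < 1L || !all(years %in% vpd_daily$years))
    stop("`years` must be at least one full year covered by the grid")
  keep <- (rep(vpd_daily$years, each = 365L) %in% years)
  v <- vpd_daily$values[, , keep, drop = FALSE]
  counts <- apply(v > c(thresholds), c(1L, 2L), sum)
  out <- counts / length(years)
  out[is.na(thresholds)] <- NA_real_
  structure(out, period = as.integer(years), thresholds = thresholds,
            class = "exceedance_clim")
}

#' Change in annual exceedance days between two climatologies
#'
#' Elementwise future minus modelled present. Refuses to compare
#' climatologies computed under different thresholds: a difference of
#' counts over different thresholds is meaningless.
#'
#' @param future,modelled_present [exceedance_days()] climatologies on the
#'   same grid and threshold map.
#' @return matrix of change in days/year with attributes `epochs` (the two
#'   period ranges) and `thresholds`.
#' @export
change_in_exceedance <- function(future, modelled_present) {
  stopifnot(inherits(future, "exceedance_clim"),
            inherits(modelled_present, "exceedance_clim"))
  if (!identical(dim(future), dim(modelled_present)))
    stop("climatologies are on different grids")
  if (!isTRUE(all.equal(attr(future, "thresholds"),
                        attr(modelled_present, "thresholds"))))
    stop("climatologies use different threshold maps; counts are not comparable")
  structure(unclass(future) - unclass(modelled_present),
            epochs = list(future = attr(future, "period"),
                          present = attr(modelled_present, "period")),
            thresholds = attr(future, "thresholds"),
            period = NULL,
            class = "exceedance_change")
}

#' @export
print.exceedance_clim <- function(x, ...) {
  p <- attr(x, "period")
  cat(sprintf("<exceedance_clim> %dx%d cells, %d-%d, days/year: ",
              nrow(x), ncol(x), min(p), max(p)))
  cat(sprintf("min %.1f, median %.1f, max %.1f\n",
              min(x, na.rm = TRUE), stats::median(x, na.rm = TRUE),
              max(x, na.rm = TRUE)))
  invisible(x)
}

#' Resample a fine density raster to the climate grid (median, zeros omitted)
#'
#' Each coarse cell takes the median of the positive fine-cell values it
#' covers; zero values are the fine products' missing-data convention and
#' are omitted. A coarse cell covering no positive fine cell is missing
#' (`NA`), not zero. The fine raster must nest in the coarse grid an
#' integer number of times along both axes.
#'
#' @param fine numeric matrix (e.g. from [simulate_density_raster()]).
#' @param n_lat,n_lon coarse grid dimensions.
#' @return numeric `(n_lat, n_lon)` matrix; the `kind` attribute of `fine`
#'   is carried over if present.
#' @export
resample_density <- function(fine, n_lat, n_lon) {
  if (nrow(fine) %% n_lat != 0L || ncol(fine) %% n_lon != 0L)
    stop("fine raster does not nest in the coarse grid")
  fr <- nrow(fine) %/% n_lat
  fc <- ncol(fine) %/% n_lon
  out <- matrix(NA_real_, n_lat, n_lon)
  for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
    block <- fine[((i - 1L) * fr + 1L):(i * fr), ((j - 1L) * fc + 1L):(j * fc)]
    pos <- block[block > 0]
    if (length(pos)) out[i, j] <- stats::median(pos)
  }
  attr(out, "kind") <- attr(fine, "kind")
  out
}

#' Exposure raster: density times change in exceedance days
#'
#' Person-days (or tonne-days) per year of exposure to critical
#' fire-activity conditions: the per-cell product of the change in annual
#' exceedance days and the cell's population count (or tonnes of
#' aboveground biomass). Bilinear in both factors; zero wherever density
#' is zero; missing where either factor is missing.
#'
#' @param change an [change_in_exceedance()] result (or matrix of
#'   days/year).
#' @param density coarse density matrix from [resample_density()]
#'   (persons or tonnes per cell).
#' @param kind `"population"` or `"biomass"`; must agree with the density
#'   raster's `kind` attribute when present.
#' @return matrix of class `"exposure_raster"` with `units` attribute
#'   `"person-days/year"` or `"tonne-days/year"`.
#' @export
exposure <- function(change, density, kind = c("population", "biomass")) {
  kind <- match.arg(kind)
  dk <- attr(density, "kind")
  if (!is.null(dk) && !identical(dk, kind))
    stop(sprintf("density raster is %s but kind = %s requested", dk, kind))
  if (!identical(dim(unclass(change)), dim(density)))
    stop("change and density are on different grids")
  structure(unclass(change) * density,
            units = if (kind == "population") "person-days/year"
                    else "tonne-days/year",
            kind = kind, epochs = attr(change, "epochs"), thresholds = NULL,
            class = "exposure_raster")
}

#' @export
print.exposure_raster <- function(x, ...) {
  cat(sprintf("<exposure_raster> %dx%d cells [%s]: total %.0f, max %.0f\n",
              nrow(x), ncol(x), attr(x, "units"),
              sum(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Write a matrix raster (density, exceedance, exposure) to CSV
#' @param m numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = FALSE)
  invisible(path)
}
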
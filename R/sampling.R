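#' Match burned-area events to daily VPD (presence rows)
#'
#' Each fire event is assigned the VPD of the nearest climate-grid cell
#' centre (great-circle distance; ties broken by lowest lat index, then
#' lowest lon index) on the day of the event. Because the fire product is
#' typically finer than the climate grid, several events can legitimately
#' map to the same climate cell-day and each still yields its own presence
#' row. Events outside the grid's spatial bounds (beyond half a cell from
#' the outermost centres) are dropped with a reported count.
#'
#' @param events a `fire_events` table (columns `lat`, `lon`, `date`,
#'   `year`, `stratum`).
#' @param vpd_daily daily VPD [climate_grid()] covering the event dates.
#' @return `data.frame` with columns `vpd, burned (=1), year, stratum,
#'   lat_idx, lon_idx, date`.
#' @export
match_presences <- function(events, vpd_daily) {
  stopifnot_units(vpd_daily, "kPa", "VPD grid")
  nd <- n_days(vpd_daily)
  if (any(events$date < 1L | events$date > nd))
    stop("event dates not covered by the VPD grid")
  half_lat <- diff(range(vpd_daily$lat)) / (2 * max(length(vpd_daily$lat) - 1L, 1L))
  half_lon <- diff(range(vpd_daily$lon)) / (2 * max(length(vpd_daily$lon) - 1L, 1L))
  inb <- events$lat >= min(vpd_daily$lat) - half_lat &
         events$lat <= max(vpd_daily$lat) + half_lat &
         events$lon >= min(vpd_daily$lon) - half_lon &
         events$lon <= max(vpd_daily$lon) + half_lon
  if (any(!inb))
    message(sum(!inb), " event(s) outside the climate grid bounds dropped")
  ev <- events[inb, , drop = FALSE]
  centres <- cbind(lon = rep(vpd_daily$lon, each = length(vpd_daily$lat)),
                   lat = rep(vpd_daily$lat, times = length(vpd_daily$lon)))
  # cells enumerated in (lat_idx, lon_idx) order so which.min's first-match
  # rule implements the documented tie-break
  nearest <- vapply(seq_len(nrow(ev)), function(k) {
    dists <- geosphere::distHaversine(c(ev$lon[k], ev$lat[k]), centres)
    which.min(dists)
  }, integer(1L))
  li <- (nearest - 1L) %% length(vpd_daily$lat) + 1L
  lj <- (nearest - 1L) %/% length(vpd_daily$lat) + 1L
  data.frame(vpd = vpd_daily$values[cbind(li, lj, ev$date)],
             burned = 1L, year = ev$year, stratum = ev$stratum,
             lat_idx = li, lon_idx = lj, date = ev$date)
}

#' Cells eligible as quasi-absences on a given date
#'
#' A cell is eligible if it lies in the stratum, is not burned on `date`,
#' and has no recorded burn in the half-open lookback window
#' `[date - lookback_years * 365, date)`. Burn history may include
#' pre-period records (day indices <= 0).
#'
#' @param cells `data.frame` with `lat_idx, lon_idx` listing the stratum's
#'   cells.
#' @param history `data.frame` with `lat_idx, lon_idx, date` of all known
#'   burns (the event table itself plus any pre-period history).
#' @param date day index of the candidate absence.
#' @param lookback_years exclusion window length in years (default 5).
#' @return the subset of `cells` that is eligible on `date`.
#' @export
eligible_absence_cells <- function(cells, history, date, lookback_years = 5L) {
  if (lookback_years < 0L) stop("`lookback_years` must be >= 0")
  key <- function(i, j) paste(i, j, sep = ":")
  lo <- date - lookback_years * 365L
  bad <- history$date >= lo & history$date < date | history$date == date
  excluded <- unique(key(history$lat_idx[bad], history$lon_idx[bad]))
  cells[!(key(cells$lat_idx, cells$lon_idx) %in% excluded), , drop = FALSE]
}

#' Sample quasi-absence rows to balance the presences
#'
#' For every stratum and calendar year, draws exactly as many absence rows
#' as there are presence rows: dates uniform over the year's days, then a
#' cell uniform among the cells eligible on that date (five-year burn
#' exclusion applied against the event table plus any pre-period history).
#' Draws are without replacement on (cell, date) pairs. Fails loudly,
#' naming the year and stratum, if a year's eligible pool cannot supply
#' the required count.
#'
#' @param presences presence rows from [match_presences()].
#' @param vpd_daily daily VPD [climate_grid()].
#' @param stratum_map character matrix `(n_lat, n_lon)` of stratum ids
#'   (`NA` outside the study area).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param history optional extra burn table (e.g. pre-period records); the
#'   presence rows themselves are always part of the exclusion history.
#' @param lookback_years exclusion window (default 5).
#' @return `data.frame` with the same columns as the presences, `burned = 0`.
#' @export
sample_quasi_absences <- function(presences, vpd_daily, stratum_map,
                                  seed = 1L, history = NULL,
                                  lookback_years = 5L) {
  stopifnot_units(vpd_daily, "kPa", "VPD grid")
  hist_all <- presences[, c("lat_idx", "lon_idx", "date")]
  if (!is.null(history))
    hist_all <- rbind(hist_all, history[, c("lat_idx", "lon_idx", "date")])
  out <- vector("list", 0L)
  with_seed(seed, {
    for (st in sort(unique(presences$stratum))) {
      cells_idx <- which(stratum_map == st, arr.ind = TRUE)
      cells <- data.frame(lat_idx = cells_idx[, 1L], lon_idx = cells_idx[, 2L])
      pres_s <- presences[presences$stratum == st, , drop = FALSE]
      for (yr in sort(unique(pres_s$year))) {
        need <- sum(pres_s$year == yr)
        yi <- match(yr, vpd_daily$years)
        day_range <- ((yi - 1L) * 365L + 1L):(yi * 365L)
        taken <- character(0L)
        rows <- vector("list", need)
        got <- 0L
        attempts <- 0L
        max_attempts <- 200L * need + 1000L
        while (got < need) {
          attempts <- attempts + 1L
          if (attempts > max_attempts)
            stop(sprintf(
              "eligible absence pool exhausted: stratum %s, year %d (%d of %d drawn)",
              st, yr, got, need))
          d <- day_range[sample.int(365L, 1L)]
          elig <- eligible_absence_cells(cells, hist_all, d, lookback_years)
          if (nrow(elig) == 0L) next
          ci <- sample.int(nrow(elig), 1L)
          k <- paste(elig$lat_idx[ci], elig$lon_idx[ci], d, sep = ":")
          if (k %in% taken) next
          taken <- c(taken, k)
          got <- got + 1L
          rows[[got]] <- data.frame(
            vpd = vpd_daily$values[cbind(elig$lat_idx[ci], elig$lon_idx[ci], d)],
            burned = 0L, year = yr, stratum = st,
            lat_idx = elig$lat_idx[ci], lon_idx = elig$lon_idx[ci], date = d)
        }
        out[[length(out) + 1L]] <- do.call(rbind, rows)
      }
    }
  })
  if (length(out) == 0L)
    return(presences[0L, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the stratified occurrence sample
#'
#' Concatenates presence and absence rows, shuffles them deterministically,
#' and records per-stratum counts. Strata present in the map but with no
#' rows are flagged unfittable in the `"counts"` attribute rather than
#' silently dropped.
#'
#' @param presences,absences row tables from [match_presences()] and
#'   [sample_quasi_absences()].
#' @param seed seed for the deterministic shuffle.
#' @param all_strata optional character vector of every stratum expected.
#' @return `data.frame` of class `"occurrence_sample"` with an attribute
#'   `"counts"` (per-stratum presences, absences, fittable flag).
#' @export
assemble_samples <- function(presences, absences, seed = 1L,
                             all_strata = NULL) {
  stopifnot(all(presences$burned == 1L), all(absences$burned == 0L))
  res <- rbind(presences, absences)
  res <- with_seed(seed, res[sample.int(nrow(res)), , drop = FALSE])
  rownames(res) <- NULL
  strata <- sort(unique(c(all_strata, presences$stratum, absences$stratum)))
  counts <- data.frame(
    stratum = strata,
    n_presence = vapply(strata, function(s) sum(presences$stratum == s), integer(1L)),
    n_absence = vapply(strata, function(s) sum(absences$stratum == s), integer(1L)))
  counts$fittable <- counts$n_presence > 0L & counts$n_absence > 0L
  attr(res, "counts") <- counts
  class(res) <- c("occurrence_sample", "data.frame")
  res
}

#' Write fire events to CSV (ISO-8601 dates)
#' @param events a `fire_events` table.
#' @param path output path.
#' @param years the calendar's year vector (origin for day indices).
#' @return `path`, invisibly.
#' @export
write_fire_events <- function(events, path, years) {
  df <- data.frame(cell_lat_idx = events$lat_idx,
                   cell_lon_idx = events$lon_idx,
                   date = day_to_iso(events$date, years),
                   stratum = events$stratum)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an occurrence sample to CSV
#' @param samples an `occurrence_sample` (or compatible) table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(
    data.frame(vpd_kpa = samples$vpd, burned = samples$burned,
               year = samples$year, stratum = samples$stratum),
    path, row.names = FALSE)
  invisible(path)
}
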
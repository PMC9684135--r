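#' Gridded climate field on a regular lat/lon grid with a no-leap calendar
#'
#' `climate_grid()` is the common currency of every stage of the pipeline: a
#' 3-D array of one meteorological variable indexed (lat, lon, time), carrying
#' coordinate vectors, units, and a 365-day no-leap calendar described by the
#' vector of covered years and the number of sub-daily steps per day.
#'
#' The time axis is implicit and regular: step `k` of day `d` (1-based day
#' index counted from 1 January of `years[1]`) lives at slice
#' `(d - 1) * steps_per_day + k`. Leap days do not exist in this calendar,
#' which sidesteps the calendar dialects of climate-model archives.
#'
#' @param values numeric array of dimension `(n_lat, n_lon, n_time)` with
#'   `n_time = 365 * length(years) * steps_per_day`.
#' @param var variable name, e.g. `"tas"`, `"dewpoint"`, `"vpd"`.
#' @param units units string; operations check units and refuse to mix them
#'   silently. One of `"degC"`, `"K"`, `"kPa"`, `"%"` or a density unit.
#' @param years integer vector of consecutive calendar years covered.
#' @param steps_per_day sub-daily steps per day; must divide 24 (24 for
#'   hourly reanalysis-like data, 8 for 3-hourly GCM-like data, 1 for daily).
#' @param lat,lon coordinate vectors (degrees); defaults place cell centres
#'   on a regular grid in a mid-latitude window.
#' @return an object of class `"climate_grid"`.
#' @export
climate_grid <- function(values, var, units, years, steps_per_day = 1,
                         lat = NULL, lon = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (lat, lon, time)")
  if (length(years) < 1L || any(diff(years) != 1L))
    stop("`years` must be a non-empty vector of consecutive calendar years")
  if (steps_per_day < 1L || 24L %% steps_per_day != 0L)
    stop("`steps_per_day` must divide 24")
  d <- dim(values)
  n_time <- 365L * length(years) * as.integer(steps_per_day)
  if (d[3L] != n_time)
    stop(sprintf("time dimension is %d but calendar implies %d", d[3L], n_time))
  if (is.null(lat)) lat <- seq(40, by = 0.25, length.out = d[1L])
  if (is.null(lon)) lon <- seq(10, by = 0.25, length.out = d[2L])
  if (length(lat) != d[1L] || length(lon) != d[2L])
    stop("coordinate vectors must match the array dimensions")
  structure(
    list(values = values, var = var, units = units,
         years = as.integer(years), steps_per_day = as.integer(steps_per_day),
         lat = as.numeric(lat), lon = as.numeric(lon)),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<climate_grid> %s [%s]  %d x %d cells, years %d-%d, %d step(s)/day\n",
              x$var, x$units, d[1L], d[2L],
              x$years[1L], x$years[length(x$years)], x$steps_per_day))
  cat(sprintf("  values: min %.3f, mean %.3f, max %.3f\n",
              min(x$values, na.rm = TRUE), mean(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

n_days <- function(grid) 365L * length(grid$years)

stopifnot_units <- function(grid, units, what) {
  if (!identical(grid$units, units))
    stop(sprintf("%s must be in %s, got %s", what, units, grid$units))
}

same_axes <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    identical(a$years, b$years) &&
    identical(a$steps_per_day, b$steps_per_day) &&
    isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

# --- no-leap calendar helpers ------------------------------------------------

.noleap_month_len <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.noleap_month_end <- cumsum(.noleap_month_len)

#' Convert day-of-year (no-leap) to calendar month
#'
#' @param doy integer day of year in 1..365.
#' @return integer month in 1..12.
#' @export
doy_to_month <- function(doy) {
  if (any(doy < 1L | doy > 365L)) stop("day of year must be in 1..365")
  findInterval(doy - 1L, c(0L, .noleap_month_end)[-13L] + 0L, rightmost.closed = FALSE)
}

#' Convert a day index to an ISO-8601 date string on the no-leap calendar
#'
#' Day index 1 is 1 January of the first year; 29 February never occurs.
#' Indices outside the year range (e.g. pre-period burn history at day
#' indices <= 0) extrapolate the calendar arithmetically.
#'
#' @param day integer day index (1-based).
#' @param years the consecutive years the index counts through.
#' @return character vector of `YYYY-MM-DD` strings.
#' @export
day_to_iso <- function(day, years) {
  yi <- as.integer(floor((day - 1L) / 365))
  doy <- (day - 1L) %% 365L + 1L
  m <- doy_to_month(doy)
  dom <- doy - c(0L, .noleap_month_end)[m]
  sprintf("%04d-%02d-%02d", years[1L] + yi, m, dom)
}

#' Parse ISO-8601 dates onto the no-leap day index
#'
#' 29 February (absent from the no-leap calendar) maps to 28 February.
#'
#' @param iso character vector `YYYY-MM-DD`.
#' @param years consecutive years of the target calendar.
#' @return integer day indices.
#' @export
iso_to_day <- function(iso, years) {
  parts <- matrix(as.integer(unlist(strsplit(iso, "-", fixed = TRUE))),
                  ncol = 3L, byrow = TRUE)
  y <- parts[, 1L]; m <- parts[, 2L]; dom <- parts[, 3L]
  leap <- m == 2L & dom == 29L
  dom[leap] <- 28L
  doy <- c(0L, .noleap_month_end)[m] + dom
  (y - years[1L]) * 365L + doy
}

# --- plain-text serialisation ------------------------------------------------

#' Write a climate grid to a long-format CSV
#'
#' A plain-text serialisation of the full grid: one row per (lat, lon, time)
#' with a header block (lines starting `#`) recording variable, units,
#' calendar and coordinates, so the file round-trips losslessly.
#'
#' @param grid a [climate_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_climate_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# var: %s", grid$var),
    sprintf("# units: %s", grid$units),
    sprintf("# years: %s", paste(grid$years, collapse = ",")),
    sprintf("# steps_per_day: %d", grid$steps_per_day),
    sprintf("# lat: %s", paste(format(grid$lat, digits = 10), collapse = ",")),
    sprintf("# lon: %s", paste(format(grid$lon, digits = 10), collapse = ","))
  ), con)
  d <- dim(grid$values)
  df <- data.frame(
    lat_idx = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    lon_idx = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    t_idx = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value = as.vector(grid$values))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a climate grid written by [write_climate_grid()]
#'
#' @param path file path.
#' @return a [climate_grid()].
#' @export
read_climate_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  if (!all(startsWith(lines, "# ")))
    stop("malformed climate grid file: missing header block: ", path)
  hdr <- function(key) {
    ln <- lines[startsWith(lines, paste0("# ", key, ":"))]
    if (length(ln) != 1L) stop("header missing field: ", key)
    sub(paste0("# ", key, ": "), "", ln, fixed = TRUE)
  }
  years <- as.integer(strsplit(hdr("years"), ",")[[1L]])
  spd <- as.integer(hdr("steps_per_day"))
  lat <- as.numeric(strsplit(hdr("lat"), ",")[[1L]])
  lon <- as.numeric(strsplit(hdr("lon"), ",")[[1L]])
  df <- utils::read.csv(path, comment.char = "#")
  arr <- array(NA_real_, dim = c(length(lat), length(lon),
                                 365L * length(years) * spd))
  arr[cbind(df$lat_idx, df$lon_idx, df$t_idx)] <- df$value
  climate_grid(arr, var = hdr("var"), units = hdr("units"), years = years,
               steps_per_day = spd, lat = lat, lon = lon)
}
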
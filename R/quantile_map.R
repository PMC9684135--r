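#' Fit an empirical quantile map between two daily series
#'
#' Bias-corrects a climate-model series against a reference climatology by
#' mapping the model's empirical quantiles onto the reference's. Quantiles
#' of both series are taken at `n_quantiles` equally spaced interior
#' probability levels; application interpolates linearly between the
#' (source, target) quantile pairs and extrapolates additively beyond the
#' outermost pair using that edge's offset. Corrected values are clamped
#' at 0 kPa.
#'
#' By default the map is fitted and applied per calendar month, so
#' seasonally varying bias is corrected within season; `by_month = FALSE`
#' pools the whole year.
#'
#' @param source numeric vector: the model-historical daily series.
#' @param target numeric vector: the reference daily series.
#' @param n_quantiles number of probability levels (default 99:
#'   percentiles 0.01..0.99).
#' @param by_month fit one map per calendar month (default TRUE).
#' @param source_doy,target_doy day-of-year (1..365) of each observation;
#'   required when `by_month = TRUE`.
#' @return an object of class `"quantile_map"`: per-month (or pooled)
#'   tables of `level, source_q, target_q`, plus a `degenerate` flag for
#'   constant source series (which get an identity-with-offset map).
#' @export
quantile_map <- function(source, target, n_quantiles = 99L,
                         by_month = TRUE, source_doy = NULL,
                         target_doy = NULL) {
  if (length(source) == 0L || length(target) == 0L)
    stop("both series must be non-empty")
  if (n_quantiles < 2L) stop("`n_quantiles` must be >= 2")
  levels <- seq_len(n_quantiles) / (n_quantiles + 1)
  fit1 <- function(src, tgt) {
    if (length(unique(src)) == 1L) {
      # constant source: no quantile structure to map; shift to the
      # target's centre and flag
      off <- stats::median(tgt) - src[1L]
      return(list(table = data.frame(level = levels,
                                     source_q = src[1L] + 0 * levels,
                                     target_q = src[1L] + off + 0 * levels),
                  degenerate = TRUE))
    }
    list(table = data.frame(
           level = levels,
           source_q = unname(stats::quantile(src, levels, type = 7)),
           target_q = unname(stats::quantile(tgt, levels, type = 7))),
         degenerate = FALSE)
  }
  if (by_month) {
    if (is.null(source_doy) || is.null(target_doy))
      stop("per-month fitting needs `source_doy` and `target_doy`")
    sm <- doy_to_month(source_doy)
    tm <- doy_to_month(target_doy)
    maps <- lapply(1:12, function(m) fit1(source[sm == m], target[tm == m]))
  } else {
    maps <- list(fit1(source, target))
  }
  structure(list(maps = maps, by_month = by_month,
                 n_quantiles = as.integer(n_quantiles),
                 degenerate = any(vapply(maps, `[[`, logical(1L), "degenerate"))),
            class = "quantile_map")
}

#' Apply a fitted quantile map to a daily series
#'
#' Values inside the fitted quantile range are corrected by piecewise
#' linear interpolation between (source, target) quantile pairs; values
#' beyond the outermost quantiles by the edge quantile's additive offset.
#' Output is clamped at 0 kPa. Rank order of the input is preserved.
#'
#' @param map a [quantile_map()].
#' @param series numeric vector to correct.
#' @param doy day-of-year of each value (needed for per-month maps).
#' @return corrected numeric vector.
#' @export
apply_quantile_map <- function(map, series, doy = NULL) {
  stopifnot(inherits(map, "quantile_map"))
  correct1 <- function(tab, x) {
    if (length(x) == 0L) return(x)
    sq <- tab$source_q; tq <- tab$target_q
    if (length(unique(sq)) == 1L) return(x + (tq[1L] - sq[1L]))
    out <- stats::approx(sq, tq, xout = x, ties = mean)$y
    lo <- x < sq[1L]; hi <- x > sq[length(sq)]
    out[lo] <- x[lo] + (tq[1L] - sq[1L])
    out[hi] <- x[hi] + (tq[length(tq)] - sq[length(sq)])
    out
  }
  if (map$by_month) {
    if (is.null(doy)) stop("per-month map needs `doy` for the series")
    m <- doy_to_month(doy)
    out <- numeric(length(series))
    for (k in 1:12) {
      sel <- m == k
      if (any(sel)) out[sel] <- correct1(map$maps[[k]]$table, series[sel])
    }
  } else {
    out <- correct1(map$maps[[1L]]$table, series)
  }
  pmax(out, 0)
}

#' @export
print.quantile_map <- function(x, ...) {
  cat(sprintf("<quantile_map> %d levels, %s%s\n", x$n_quantiles,
              if (x$by_month) "per calendar month" else "pooled all-year",
              if (x$degenerate) " [degenerate source flagged]" else ""))
  invisible(x)
}

#' Bias-correct a GCM-like VPD grid cell by cell
#'
#' Fits a [quantile_map()] per climate cell from the model-historical grid
#' to the reference grid, then applies it to `apply_to` (the historical
#' grid itself, or a future grid — correcting the future series with the
#' historical-vs-reference map is the standard use).
#'
#' @param model_hist,reference daily VPD [climate_grid()]s on the same
#'   grid (time lengths may differ).
#' @param apply_to daily VPD [climate_grid()] to correct.
#' @param ... passed to [quantile_map()] (`n_quantiles`, `by_month`).
#' @return corrected [climate_grid()] on `apply_to`'s axes.
#' @export
bias_correct_grid <- function(model_hist, reference, apply_to = model_hist,
                              ...) {
  for (g in list(model_hist, reference, apply_to))
    stopifnot_units(g, "kPa", "VPD grid")
  if (!identical(dim(model_hist$values)[1:2], dim(reference$values)[1:2]) ||
      !identical(dim(model_hist$values)[1:2], dim(apply_to$values)[1:2]))
    stop("grids must share the same spatial dimensions")
  doy_of <- function(g) rep_len(rep(1:365, length(g$years)), dim(g$values)[3L])
  sd_ <- doy_of(model_hist); rd <- doy_of(reference); ad <- doy_of(apply_to)
  out <- apply_to$values
  for (i in seq_len(dim(out)[1L])) for (j in seq_len(dim(out)[2L])) {
    qm <- quantile_map(model_hist$values[i, j, ], reference$values[i, j, ],
                       source_doy = sd_, target_doy = rd, ...)
    out[i, j, ] <- apply_quantile_map(qm, apply_to$values[i, j, ], doy = ad)
  }
  climate_grid(out, "vpd", "kPa", apply_to$years, apply_to$steps_per_day,
               lat = apply_to$lat, lon = apply_to$lon)
}

#' Climate-change signal by the delta convention
#'
#' Change is always modelled-future minus modelled-present, so any
#' constant model bias cancels; the observed climatology never enters the
#' difference. Works elementwise on matrices (e.g. exceedance-day
#' climatologies) or on [climate_grid()]s with identical axes.
#'
#' @param future,modelled_present same-shaped matrices or grids.
#' @return elementwise `future - modelled_present`, same shape/class as
#'   the inputs.
#' @export
delta_change <- function(future, modelled_present) {
  if (inherits(future, "climate_grid") &&
      inherits(modelled_present, "climate_grid")) {
    if (!same_axes(future, modelled_present))
      stop("grids have mismatched axes")
    out <- future
    out$values <- future$values - modelled_present$values
    return(out)
  }
  if (!identical(dim(future), dim(modelled_present)))
    stop("inputs have mismatched dimensions")
  future - modelled_present
}
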
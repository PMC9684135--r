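# Small fixture builders shared across the suite. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# Prospective occurrence sample with VPD uniform on (0, 2 * threshold):
# symmetric about the planted threshold, so labels are balanced in
# expectation and the balanced case-control design introduces no
# intercept shift — the design under which threshold recovery is exact.
planted_sample <- function(n, beta0, beta1, seed, stratum = "S1") {
  thr <- -beta0 / beta1
  withr::with_seed(seed, {
    v <- stats::runif(n, 0, 2 * thr)
    y <- stats::rbinom(n, 1L, stats::plogis(beta0 + beta1 * v))
    data.frame(vpd = v, burned = y, year = 2003L, stratum = stratum)
  })
}

# a tiny daily VPD grid with hand-settable values
tiny_vpd_grid <- function(values, years = 2003L, n_lat = dim(values)[1L],
                          n_lon = dim(values)[2L]) {
  climate_grid(values, "vpd", "kPa", years, 1L)
}

tiny_world <- function(n = 2L, years = 2003:2004, spd = 8L, seed = 11L)
  world_spec(n, n, years, steps_per_day = spd, seed = seed)

# one-row fire event at a cell centre of `grid`
event_at <- function(grid, i, j, day, stratum = "S1") {
  data.frame(lat_idx = i, lon_idx = j, lat = grid$lat[i], lon = grid$lon[j],
             date = day, year = grid$years[(day - 1L) %/% 365L + 1L],
             stratum = stratum)
}

# brute-force Mann-Whitney AUC: fraction of (positive, negative) pairs
# ranked correctly, ties counted half — the O(n^2) oracle
auc_brute <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}
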
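# Presence matching, the five-year exclusion, and balanced quasi-absence
# sampling.

test_that("presences take the VPD of the containing cell on the event day", {
  grid <- tiny_vpd_grid(array(seq_len(2 * 2 * 365) / 100, c(2, 2, 365)))
  ev <- event_at(grid, 2, 1, day = 10)
  pres <- match_presences(ev, grid)
  expect_equal(nrow(pres), 1L)
  expect_equal(pres$vpd, grid$values[2, 1, 10])
  expect_equal(pres$burned, 1L)
})

test_that("multiple events in one climate cell-day each yield a presence row", {
  grid <- tiny_vpd_grid(array(1.5, c(2, 2, 365)))
  ev <- do.call(rbind, replicate(3, event_at(grid, 1, 1, day = 50),
                                 simplify = FALSE))
  # jitter within the cell: still nearest to (1,1)
  ev$lat <- ev$lat + c(0, 0.05, -0.05)
  pres <- match_presences(ev, grid)
  expect_equal(nrow(pres), 3L)
  expect_true(all(pres$lat_idx == 1L & pres$lon_idx == 1L))
  expect_true(all(pres$vpd == 1.5))
})

test_that("equidistant events resolve deterministically and out-of-bounds are dropped", {
  grid <- tiny_vpd_grid(array(runif(2 * 2 * 365), c(2, 2, 365)))
  mid <- data.frame(lat_idx = NA, lon_idx = NA,
                    lat = mean(grid$lat[1:2]), lon = grid$lon[1],
                    date = 5L, year = 2003L, stratum = "S1")
  p1 <- match_presences(mid, grid)
  p2 <- match_presences(mid, grid)
  expect_identical(p1, p2)
  expect_equal(p1$lat_idx, 1L)  # tie broken toward the lowest lat index

  far <- mid; far$lat <- 80
  expect_message(p3 <- match_presences(rbind(mid, far), grid), "dropped")
  expect_equal(nrow(p3), 1L)
})

test_that("five-year exclusion returns exactly the enumerated eligible set", {
  # 10 cells in a row; cell 1 burned 4 years before d (excluded), cell 2
  # burned 6 years before d (eligible): 9 eligible
  cells <- data.frame(lat_idx = 1:10, lon_idx = 1L)
  d <- 7L * 365L
  history <- data.frame(lat_idx = c(1L, 2L), lon_idx = 1L,
                        date = c(d - 4L * 365L, d - 6L * 365L))
  elig <- eligible_absence_cells(cells, history, d)
  expect_equal(nrow(elig), 9L)
  expect_false(1L %in% elig$lat_idx)
  expect_true(2L %in% elig$lat_idx)

  # boundary: a burn exactly 5 years ago is inside the half-open window
  hb <- data.frame(lat_idx = 3L, lon_idx = 1L, date = d - 5L * 365L)
  expect_false(3L %in% eligible_absence_cells(cells, hb, d)$lat_idx)
  # a burn on the day itself excludes (unburned-on-date requirement)
  hd <- data.frame(lat_idx = 4L, lon_idx = 1L, date = d)
  expect_false(4L %in% eligible_absence_cells(cells, hd, d)$lat_idx)

  # lookback 0: only the same-day burn excludes
  h0 <- data.frame(lat_idx = c(5L, 6L), lon_idx = 1L, date = c(d, d - 1L))
  e0 <- eligible_absence_cells(cells, h0, d, lookback_years = 0L)
  expect_false(5L %in% e0$lat_idx)
  expect_true(6L %in% e0$lat_idx)

  # no history: everything eligible
  expect_equal(nrow(eligible_absence_cells(cells, history[0, ], d)), 10L)
})

test_that("absences balance presences per year and stratum, exactly", {
  grid <- tiny_vpd_grid(array(runif(5 * 5 * 730, 0, 3), c(5, 5, 730)),
                        years = 2003:2004)
  smap <- matrix("S1", 5, 5)
  # 100 presences in 2003, 50 in 2004, hand-built
  pres <- withr::with_seed(4L, data.frame(
    vpd = runif(150, 0, 3), burned = 1L,
    year = rep(c(2003L, 2004L), c(100L, 50L)),
    stratum = "S1",
    lat_idx = sample(5L, 150L, TRUE), lon_idx = sample(5L, 150L, TRUE),
    date = c(sample(365L, 100L, TRUE), 365L + sample(365L, 50L, TRUE))))
  ab <- sample_quasi_absences(pres, grid, smap, seed = 9L, lookback_years = 0L)
  expect_equal(c(sum(ab$year == 2003L), sum(ab$year == 2004L)), c(100L, 50L))
  expect_equal(nrow(ab), 150L)
  expect_true(all(ab$burned == 0L))
  # no drawn (cell, date) pair duplicates another
  expect_false(any(duplicated(ab[, c("lat_idx", "lon_idx", "date")])))

  # seeded determinism
  ab2 <- sample_quasi_absences(pres, grid, smap, seed = 9L, lookback_years = 0L)
  expect_identical(ab, ab2)

  # assembly preserves balance and reports counts
  samp <- assemble_samples(pres, ab, seed = 2L)
  expect_equal(nrow(samp), 300L)
  expect_equal(mean(samp$burned), 0.5)
  counts <- attr(samp, "counts")
  expect_equal(counts$n_presence, 150L)
  expect_true(all(counts$fittable))
})

test_that("no absence row violates the exclusion window (history replay)", {
  spec <- world_spec(4, 4, 2003:2005, 1L, seed = 41L)
  grid <- simulate_vpd_grid(spec, mean = 1.5, sd = 0.6)
  # threshold 3.6 kPa sits far in the tail of the N(1.5, 0.6) marginal, so
  # burns are rare and the exclusion filter leaves a usable pool to sample
  ev <- simulate_fire_occurrence(grid, fire_law(-18, 5), seed = 12L,
                                 history_years = 5L, history_rate = 0.001)
  pres <- match_presences(ev, grid)
  hist <- attr(ev, "history")
  ab <- sample_quasi_absences(pres, grid, matrix("S1", 4, 4), seed = 13L,
                              history = hist)
  all_burns <- rbind(pres[, c("lat_idx", "lon_idx", "date")],
                     hist[, c("lat_idx", "lon_idx", "date")])
  for (k in seq_len(nrow(ab))) {
    same_cell <- all_burns$lat_idx == ab$lat_idx[k] &
                 all_burns$lon_idx == ab$lon_idx[k]
    viol <- same_cell & all_burns$date <= ab$date[k] &
            all_burns$date > ab$date[k] - 5L * 365L
    expect_false(any(viol))
  }
})

test_that("eligible cell draws are uniform across cells (chi-squared sanity)", {
  grid <- tiny_vpd_grid(array(1, c(2, 2, 365)))
  smap <- matrix("S1", 2, 2)
  pres <- data.frame(vpd = 1, burned = 1L, year = 2003L, stratum = "S1",
                     lat_idx = 1L, lon_idx = 1L, date = 400L)
  pres$date <- 100L
  draws <- t(vapply(1:400, function(s) {
    a <- sample_quasi_absences(pres, grid, smap, seed = s, lookback_years = 0L)
    c(a$lat_idx, a$lon_idx)
  }, integer(2L)))
  cell <- paste(draws[, 1L], draws[, 2L])
  expect_gt(stats::chisq.test(table(factor(cell, levels =
    c("1 1", "1 2", "2 1", "2 2"))))$p.value, 1e-3)
})

test_that("exhausted pools fail loudly with year and stratum named", {
  grid <- tiny_vpd_grid(array(1, c(1, 1, 365)))
  smap <- matrix("S1", 1, 1)
  pres <- data.frame(vpd = 1, burned = 1L, year = 2003L, stratum = "S1",
                     lat_idx = 1L, lon_idx = 1L, date = c(1L, 2L))
  # the single cell burns on day 1: no later date in the year escapes the
  # five-year window, so nothing is ever eligible
  expect_error(sample_quasi_absences(pres, grid, smap, seed = 1L),
               "stratum S1, year 2003")
})
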
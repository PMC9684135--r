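# The seeded generators: determinism, construction constraints, and the
# statistical structure the downstream stages rely on.

test_that("world_spec and fire_law validate their invariants", {
  expect_error(world_spec(0, 2, 2003), "at least one cell")
  expect_error(world_spec(2, 2, c(2003, 2005)), "consecutive")
  expect_error(world_spec(2, 2, 2003, steps_per_day = 7), "divide 24")
  expect_error(fire_law(-5, 0), "positive")
  expect_error(fire_law(-5, -2), "positive")
  expect_equal(fire_law(-5, 2)$threshold, 2.5)
})

test_that("climate generator is bit-identical under a fixed seed", {
  a <- simulate_climate(tiny_world(seed = 99L))
  b <- simulate_climate(tiny_world(seed = 99L))
  expect_identical(a$temperature$values, b$temperature$values)
  expect_identical(a$dewpoint$values, b$dewpoint$values)
  c <- simulate_climate(tiny_world(seed = 100L))
  expect_false(identical(a$temperature$values, c$temperature$values))
})

test_that("climate fields have the declared shape and dew point never exceeds temperature", {
  spec <- world_spec(2, 2, 2003L, steps_per_day = 24L, seed = 3L)
  sim <- simulate_climate(spec)
  expect_equal(dim(sim$temperature$values), c(2, 2, 365 * 24))
  expect_equal(dim(sim$dewpoint$values), c(2, 2, 365 * 24))
  expect_true(all(sim$dewpoint$values <= sim$temperature$values))
  # the constraint is structural: it holds with zero noise too
  sim0 <- simulate_climate(spec, noise_sd = 0, regional_sd = 0, dep_sd = 0)
  expect_true(all(sim0$dewpoint$values <= sim0$temperature$values))
  # annual cycle present: warm-season days exceed cold-season days
  doy <- rep(1:365, each = 24)
  warm <- mean(sim0$temperature$values[1, 1, doy %in% 180:220])
  cold <- mean(sim0$temperature$values[1, 1, doy %in% 1:40])
  expect_gt(warm, cold)
})

test_that("fire occurrence follows the planted logistic law", {
  # degenerate laws first
  vpd1 <- tiny_vpd_grid(array(1, c(2, 2, 365)))
  none <- simulate_fire_occurrence(vpd1, fire_law(-60, 2), seed = 1L)
  expect_equal(nrow(none), 0L)
  all_burn <- simulate_fire_occurrence(vpd1, fire_law(0, 60), seed = 1L)
  expect_equal(nrow(all_burn), 2L * 2L * 365L)

  # empirical burn fraction vs numerical integration of the logistic over
  # the uniform VPD marginal (the [DERIVED] oracle), 1e5 cell-days
  law <- fire_law(-5, 2)
  vals2 <- withr::with_seed(21L, runif(20 * 20 * 365, 0, 5))  # 1.46e5 cell-days
  grid <- tiny_vpd_grid(array(vals2, c(20, 20, 365)))
  ev <- simulate_fire_occurrence(grid, law, seed = 8L)
  p_true <- integrate(function(v) plogis(-5 + 2 * v) / 5, 0, 5)$value
  n_cd <- length(vals2)
  mc_se <- sqrt(p_true * (1 - p_true) / n_cd)
  expect_lt(abs(nrow(ev) / n_cd - p_true), 3 * mc_se)
})

test_that("fire occurrence is seed-deterministic and emits an independent history", {
  grid <- tiny_vpd_grid(array(runif(4 * 365, 0, 4), c(2, 2, 365)))
  a <- simulate_fire_occurrence(grid, fire_law(-4, 2), seed = 5L,
                                history_years = 5L, history_rate = 0.01)
  b <- simulate_fire_occurrence(grid, fire_law(-4, 2), seed = 5L,
                                history_years = 5L, history_rate = 0.01)
  expect_identical(as.data.frame(a), as.data.frame(b))
  h <- attr(a, "history")
  expect_true(all(h$date <= 0))
  expect_gt(nrow(h), 0L)
})

test_that("GCM-like distortion is affine with retained parameters", {
  spec <- world_spec(2, 2, 2003:2004, 1L, seed = 17L)
  ref <- simulate_vpd_grid(spec, mean = 2, sd = 0.5)
  ident <- simulate_gcm_like(ref, 0, 1, 0)
  expect_identical(ident$historical$values, ref$values)
  expect_identical(ident$future$values, ref$values)

  g <- simulate_gcm_like(ref, bias_shift = 0.3, bias_scale = 1.2,
                         future_delta = 0.5)
  expect_equal(mean(g$future$values - g$historical$values), 0.5)
  expect_equal(sd(g$historical$values), 1.2 * sd(ref$values), tolerance = 1e-9)
  expect_equal(g$distortion,
               list(bias_shift = 0.3, bias_scale = 1.2, future_delta = 0.5))
  expect_error(simulate_gcm_like(ref, 0, -1, 0), "positive")
})

test_that("direct VPD generator has the planted Gaussian marginal", {
  spec <- world_spec(6, 6, 2003:2005, 1L, seed = 23L)
  g <- simulate_vpd_grid(spec, mean = 2, sd = 0.5, ar1 = 0)
  x <- as.vector(g$values)
  n <- length(x)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 2), 3 * 0.5 / sqrt(n))
  expect_equal(sd(x), 0.5, tolerance = 0.02)
})

test_that("density rasters plant the requested zero fraction and nest in the grid", {
  spec <- world_spec(5, 5, 2003L, 1L, seed = 31L)
  r0 <- simulate_density_raster(spec, "population", zero_fraction = 0)
  expect_true(all(r0 > 0))
  r <- simulate_density_raster(spec, "biomass", zero_fraction = 0.5,
                               refine = 20L)  # 100x100 = 1e4 cells
  n <- length(r)
  expect_equal(n, 1e4)
  expect_lt(abs(sum(r == 0) - 0.5 * n), 3 * sqrt(n * 0.25))
  expect_true(all(r >= 0))
  # nesting arithmetic: refine 4 puts 16 fine cells under each coarse cell
  r4 <- simulate_density_raster(spec, "population", 0.1, refine = 4L)
  expect_equal(dim(r4), c(20L, 20L))
  expect_equal((nrow(r4) / spec$n_lat) * (ncol(r4) / spec$n_lon), 16)
  expect_error(simulate_density_raster(spec, "population", 1), "zero_fraction")
})
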
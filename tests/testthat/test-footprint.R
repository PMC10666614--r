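# Volume-proportional sizing, accumulation zones and footprint assembly.

test_that("buffer size follows the log-proportional rule with clamping", {
  # the catalog maximum always receives the cap
  expect_equal(buffer_size(10000, 10000), 50)
  # half the log of the maximum receives half the cap
  expect_equal(buffer_size(100, 10000), 25)
  # log(1) = 0: the raw formula returns 0, the floor applies
  cfg <- sizing_config(min_buffer_m = 5)
  expect_equal(buffer_size(1, 10000, cfg), 5)
  # base invariance: the ratio of logs does not depend on the base
  expect_equal(buffer_size(exp(3), exp(6)), 25)
})

test_that("buffer size is monotone in quantity and bounded", {
  q <- sort(exp(runif(50, 0, log(10000))))
  s <- buffer_size(q, 10000, sizing_config(min_buffer_m = 10))
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 10 & s <= 50))
})

test_that("buffer size rejects out-of-order or degenerate inputs", {
  expect_error(buffer_size(20000, 10000), "q_max")
  expect_error(buffer_size(0.5, 1), "q_max")
  expect_error(buffer_size(-3, 100), "positive")
})

test_that("validation splits a draft catalog into kept and dropped", {
  val <- validate_spills(drafts_with_invalid(1909, 432))
  expect_equal(nrow(val$kept), 1477)
  expect_equal(nrow(val$dropped), 432)
  expect_equal(sum(val$report$count), 1909)

  empty <- validate_spills(tibble::tibble(spill_id = integer(),
                                          x = numeric(), y = numeric(),
                                          quantity = numeric()))
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$dropped), 0)

  one <- validate_spills(tibble::tibble(spill_id = 1, x = 0, y = 0,
                                        quantity = -5))
  expect_equal(one$dropped$drop_reason, "quantity")
})

test_that("an uphill-surrounded centre keeps only its own disc", {
  # bowl: every neighbour strictly higher than the centre
  dem <- make_dem("basin", 11, 11, cell_size = 10, basin_depth = 30)
  pts <- grid_points(dem)
  ctr <- cell_center(dem, 6, 6)
  ce <- dem$values[6, 6]
  z <- accumulation_zone(ctr$x, ctr$y, ce, pts, radius = 40)
  expect_equal(geom_area(z), pi * 4.5^2, tolerance = 0.02)
  # nothing beyond the centre disc
  far <- geom_distance_points(z, ctr$x + 15, ctr$y)
  expect_gt(far, 5)
})

test_that("an all-downhill neighbourhood fills the potential zone", {
  # summit: every neighbour strictly lower; convex hull of all member
  # discs covers the whole potential disc
  dem <- make_dem("basin", 11, 11, cell_size = 10, basin_depth = -30)
  pts <- grid_points(dem)
  ctr <- cell_center(dem, 6, 6)
  ce <- dem$values[6, 6]
  cfg <- sizing_config(concavity = 1)
  z <- accumulation_zone(ctr$x, ctr$y, ce, pts, radius = 40, cfg = cfg)
  expect_equal(geom_area(z), pi * 40^2, tolerance = 0.02)
})

test_that("a half-plane of lower ground yields a one-sided zone", {
  # west of centre 1 m lower, east 1 m higher
  z <- outer(rep(0, 21), c(rep(-1, 10), 0, rep(1, 10)), FUN = function(a, b) 300 + b)
  dem <- elevation_grid(z, 0, 210, 10)
  pts <- grid_points(dem)
  ctr <- cell_center(dem, 11, 11)
  ce <- dem$values[11, 11]
  zone <- accumulation_zone(ctr$x, ctr$y, ce, pts, radius = 45)
  # the below-elevation mask is the west half: sample points west are in,
  # east beyond the centre's own disc are out
  expect_true(geom_contains_points(zone, ctr$x - 30, ctr$y))
  expect_false(geom_contains_points(zone, ctr$x + 30, ctr$y))
  expect_false(geom_contains_points(zone, ctr$x + 15, ctr$y + 15))
  # the centre itself is always covered
  expect_true(geom_contains_points(zone, ctr$x, ctr$y))
})

test_that("zones stay inside the dilated potential disc and keep positive area", {
  dem <- make_dem("random_smooth", 25, 25, cell_size = 10, seed = 5)
  pts <- grid_points(dem)
  set.seed(6)
  for (i in 1:5) {
    r <- sample(3:23, 1); cc <- sample(3:23, 1)
    ctr <- cell_center(dem, r, cc)
    radius <- runif(1, 15, 50)
    z <- accumulation_zone(ctr$x, ctr$y, dem$values[r, cc], pts, radius)
    expect_gt(geom_area(z), 0)
    bb <- geom_bbox(z)
    lim <- radius + attr(pts, "point_buffer") + 1e-6
    expect_true(all(abs(c(bb - c(ctr$x, ctr$y, ctr$x, ctr$y))) <= lim))
  }
})

test_that("a spill at a pit collapses to a single accumulation zone", {
  dem <- make_dem("basin", 11, 11, cell_size = 10)
  fd <- flow_direction(dem)
  ctr <- cell_center(dem, 6, 6)
  fp <- build_footprint(list(spill_id = "a", x = ctr$x, y = ctr$y,
                             quantity = 5000),
                        dem, fd, q_max = 10000)
  expect_true(geom_is_empty(fp$corridor))
  expect_equal(fp$termination_reason, "pit")
  expect_equal(fp$end_x, fp$x)
  expect_equal(geom_area(fp$footprint), geom_area(fp$start_zone),
               tolerance = 1e-6)
})

test_that("a plane footprint is two zones joined by a straight corridor", {
  dem <- make_dem("plane", 9, 30, cell_size = 10, slope_x = 0.05)
  fd <- flow_direction(dem, "flow_outward")
  ctr <- cell_center(dem, 5, 1)
  fp <- build_footprint(list(spill_id = "p", x = ctr$x, y = ctr$y,
                             quantity = 10000),
                        dem, fd, q_max = 10000)
  expect_equal(fp$termination_reason, "edge")
  L <- fp$trace$length_m
  expect_equal(L, 290)
  expect_equal(geom_area(fp$corridor), L * 30 + pi * 15^2, tolerance = 0.01)
  # union area never exceeds the sum of the parts
  expect_lte(geom_area(fp$footprint),
             geom_area(fp$start_zone) + geom_area(fp$corridor) +
               geom_area(fp$end_zone) + 1e-9)
})

test_that("same location, different volumes: same traceline, nested sizing", {
  dem <- make_dem("random_smooth", 20, 20, cell_size = 10, seed = 9)
  fd <- flow_direction(dem)
  ctr <- cell_center(dem, 10, 4)
  small <- build_footprint(list(spill_id = 1, x = ctr$x, y = ctr$y,
                                quantity = 100), dem, fd, q_max = 10000)
  large <- build_footprint(list(spill_id = 2, x = ctr$x, y = ctr$y,
                                quantity = 10000), dem, fd, q_max = 10000)
  expect_identical(small$trace$path, large$trace$path)
  expect_lt(small$buffer_size_m, large$buffer_size_m)
})

test_that("footprint construction is deterministic", {
  dem <- make_dem("random_smooth", 20, 20, cell_size = 10, seed = 4)
  sp <- make_spills(dem, 5, seed = 2)
  a <- build_footprints(sp, dem)
  set.seed(31415); runif(10)   # unrelated RNG activity must not matter
  b <- build_footprints(sp, dem)
  expect_identical(a$footprint, b$footprint)
  expect_identical(a$buffer_size_m, b$buffer_size_m)
})

test_that("build_footprints validates and reports", {
  dem <- make_dem("plane", 10, 10, cell_size = 10)
  sp <- make_spills(dem, 10, invalid_fraction = 0.2, seed = 8)
  fps <- build_footprints(sp, dem)
  expect_equal(nrow(fps), 8)
  rep <- attr(fps, "validation")
  expect_equal(sum(rep$count), 10)
  expect_error(build_footprint(list(spill_id = 1, x = NA, y = 0, quantity = 1),
                               dem, flow_direction(dem), 100),
               "invalid spill")
})
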
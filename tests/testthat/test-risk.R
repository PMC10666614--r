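# Exposure metrics, union semantics, classification, prioritisation and
# zonal overlays, checked against hand-built geometry.

sq_fp <- function(xmin, ymin, side = 1) {
  geom_rect(xmin, ymin, xmin + side, ymin + side)
}

test_that("union semantics collapse duplicates; chronic mode keeps them", {
  a <- sq_fp(0, 0)
  b <- sq_fp(0.5, 0)           # 50% overlap with a
  expect_equal(geom_area(union_footprints(list(a, a))), 1, tolerance = 1e-6)
  u <- union_footprints(list(a, b), "union")
  ch <- union_footprints(list(a, b), "chronic_sum")
  expect_equal(geom_area(u), 1.5, tolerance = 1e-6)
  expect_equal(sum(vapply(ch, geom_area, numeric(1))), 2)
  # disjoint additivity
  expect_equal(geom_area(union_footprints(list(a, sq_fp(5, 5)))), 2,
               tolerance = 1e-6)
  expect_true(geom_is_empty(union_footprints(list())))
})

make_test_tract <- function(population = 100) {
  zone_table("ct1", "tract", list(geom_rect(0, 0, 200, 200)), population)
}

test_pop <- function() {
  population_cells(c(50, 150, 50, 150), c(50, 50, 150, 150),
                   count = c(3, 4, 5, 6), pop_buffer = 35)
}

test_that("population risk counts whole cells whose discs touch the footprints", {
  tract <- make_test_tract(100)
  pop <- test_pop()
  # footprint reaching the discs of the two southern cells only: 3 + 4 = 7
  fp <- list(geom_rect(30, 40, 170, 60))
  row <- population_risk(fp, tract, pop)
  expect_equal(row$value, 0.07)
  expect_equal(row$exposed_population, 7)
  expect_equal(row$n_spills, 1)

  # no footprint touches the tract
  none <- population_risk(list(geom_rect(500, 500, 510, 510)), tract, pop)
  expect_equal(none$value, 0)
  expect_equal(none$n_spills, 0)

  # duplicating the footprint list changes nothing under union semantics
  dup <- population_risk(c(fp, fp), tract, pop)
  expect_equal(dup$value, row$value)
})

test_that("a disc grazing the footprint counts in full", {
  tract <- make_test_tract(10)
  pop <- population_cells(100, 100, 10, pop_buffer = 35)
  # footprint edge 34 m from the cell centre: inside the 35 m disc
  touching <- list(geom_rect(134, 80, 160, 120))
  expect_equal(population_risk(touching, tract, pop)$exposed_population, 10)
  # 36 m away: outside
  missing <- list(geom_rect(136, 80, 160, 120))
  expect_equal(population_risk(missing, tract, pop)$exposed_population, 0)
})

test_that("zero-population tracts are handled and >1 ratios warned", {
  pop <- test_pop()
  fp <- list(geom_rect(30, 40, 170, 60))
  empty_tract <- make_test_tract(0)
  row <- population_risk(fp, empty_tract, pop)
  expect_true(is.na(row$value))
  expect_equal(row$flag, "undefined")
  no_fp <- population_risk(list(geom_rect(500, 500, 501, 501)),
                           empty_tract, pop)
  expect_equal(no_fp$value, 0)

  tiny <- make_test_tract(2)
  expect_warning(population_risk(fp, tiny, pop), "pRisk above 1")

  sw <- zone_table("sw", "subwatershed", list(geom_rect(0, 0, 1, 1)))
  expect_error(population_risk(fp, sw, pop), "tract")
})

test_that("land risk is the clipped-area ratio", {
  # the printed-areas check: a 3,708 m^2 footprint wholly inside a
  # 1,398,358 m^2 subwatershed
  sw <- zone_table("a", "subwatershed",
                   list(geom_rect(0, 0, 1000, 1398.358)))
  fp <- list(geom_rect(100, 100, 160, 161.8))   # 60 x 61.8 = 3708
  row <- land_risk(fp, sw)
  expect_equal(row$value, 3708 / 1398358, tolerance = 1e-6)
  expect_equal(row$exposed_area, 3708, tolerance = 1e-6)

  # full cover reaches the upper bound
  full <- land_risk(list(geom_rect(-10, -10, 1010, 1410)), sw)
  expect_equal(full$value, 1, tolerance = 1e-6)

  # half-in/half-out rectangle: only the inside half counts
  half <- land_risk(list(geom_rect(-50, 0, 50, 100)), sw)
  expect_equal(half$exposed_area, 50 * 100, tolerance = 1e-6)
  expect_equal(half$value, 5000 / 1398358, tolerance = 1e-6)

  expect_error(land_risk(fp, zone_table("t", "tract",
                                        list(geom_rect(0, 0, 1, 1)), 5)),
               "subwatershed")
})

test_that("risk metrics are idempotent under union and monotone in footprints", {
  dem <- make_dem("random_smooth", 25, 25, cell_size = 10, seed = 13)
  sp <- make_spills(dem, 8, duplicate_pairs = 2, seed = 13)
  fps <- build_footprints(sp, dem)
  pop <- make_population(dem, cell_size = 90, count = 2)
  tracts <- make_zones(dem, 2, 2, "tract", default_population = 50)
  sws <- make_zones(dem, 2, 2, "subwatershed")

  pr <- population_risk(fps, tracts, pop)
  lr <- land_risk(fps, sws)

  # duplicating every footprint leaves union-mode metrics unchanged
  doubled <- c(fps$footprint, fps$footprint)
  expect_equal(population_risk(doubled, tracts, pop)$value, pr$value)
  expect_equal(land_risk(doubled, sws)$value, lr$value)

  # adding a footprint never decreases either metric
  pr_sub <- population_risk(fps$footprint[1:4], tracts, pop)
  lr_sub <- land_risk(fps$footprint[1:4], sws)
  # 1e-9 slack absorbs clipping-engine snapping noise on equal ratios
  expect_true(all(pr$value >= pr_sub$value - 1e-9))
  expect_true(all(lr$value >= lr_sub$value - 1e-9))

  # chronic accounting dominates union accounting row-wise
  pr_ch <- population_risk(fps, tracts, pop, mode = "chronic_sum")
  lr_ch <- land_risk(fps, sws, mode = "chronic_sum")
  expect_true(all(pr_ch$value >= pr$value - 1e-9))
  expect_true(all(lr_ch$value >= lr$value - 1e-9))
  expect_true(all(lr$value >= 0 & lr$value <= 1))
})

test_that("quantile classification matches a sort-and-split oracle", {
  rows <- tibble::tibble(zone_id = 1:10, value = 1:10)
  cls <- classify_quantiles(rows, k = 5)
  expect_equal(cls$quantile_class, rep(1:5, each = 2))

  # a fully tied vector collapses into a single shared class
  flat <- tibble::tibble(zone_id = 1:4, value = rep(7, 4))
  suppressMessages(cf <- classify_quantiles(flat, k = 5))
  expect_equal(length(unique(cf$quantile_class)), 1)
  expect_true(attr(cf, "collapsed"))

  # 100 distinct random values: 20 per class, agreeing with sorting
  set.seed(42)
  v <- sample(stats::rnorm(100))
  rows <- tibble::tibble(zone_id = seq_along(v), value = v)
  cls <- classify_quantiles(rows, k = 5)
  expect_equal(unname(table(cls$quantile_class)), rep(20L, 5),
               ignore_attr = TRUE)
  oracle <- rep(1:5, each = 20)[match(v, sort(v))]
  expect_equal(cls$quantile_class, oracle)

  # tied values share the lower class
  rows <- tibble::tibble(zone_id = 1:4, value = c(1, 2, 2, 3))
  cls <- suppressMessages(classify_quantiles(rows, k = 2))
  expect_equal(cls$quantile_class, c(1L, 1L, 1L, 2L))
})

test_that("prioritisation intersects the top classes geometrically", {
  tracts <- zone_table(c("t1", "t2"), "tract",
                       list(geom_rect(0, 0, 100, 100),
                            geom_rect(100, 0, 200, 100)),
                       population = c(10, 10))
  sws <- zone_table(c("s1", "s2"), "subwatershed",
                    list(geom_rect(20, 20, 60, 60),
                         geom_rect(120, 20, 160, 60)))
  p_rows <- classify_quantiles(
    tibble::tibble(zone_id = c("t1", "t2"), value = c(0.9, 0.1)), k = 2)
  l_rows <- classify_quantiles(
    tibble::tibble(zone_id = c("s1", "s2"), value = c(0.8, 0.2)), k = 2)

  # top tract t1 contains top subwatershed s1 entirely
  sites <- prioritize(p_rows, l_rows, tracts, sws)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$tract_id, "t1")
  expect_equal(geom_area(sites$geometry[[1]]), 1600, tolerance = 1e-6)
  expect_equal(c(sites$point_x, sites$point_y), c(40, 40))

  # disjoint top classes produce no sites
  l_rows2 <- classify_quantiles(
    tibble::tibble(zone_id = c("s1", "s2"), value = c(0.2, 0.8)), k = 2)
  expect_equal(nrow(prioritize(p_rows, l_rows2, tracts, sws)), 0)

  # a known tiling: count equals the hand-enumerated pair overlaps
  tr3 <- make_zones(c(xmin = 0, ymin = 0, xmax = 300, ymax = 300),
                    1, 3, "tract", default_population = 1)
  sw3 <- make_zones(c(xmin = 0, ymin = 0, xmax = 300, ymax = 300),
                    3, 1, "subwatershed")
  p3 <- classify_quantiles(tibble::tibble(zone_id = tr3$zone_id,
                                          value = c(3, 2, 1)), k = 3)
  l3 <- classify_quantiles(tibble::tibble(zone_id = sw3$zone_id,
                                          value = c(1, 2, 3)), k = 3)
  s3 <- prioritize(p3, l3, tr3, sw3)     # every column crosses every row once
  expect_equal(nrow(s3), 1)
  expect_equal(geom_area(s3$geometry[[1]]), 100 * 100, tolerance = 1e-6)

  expect_error(prioritize(p3, l_rows, tr3, sws), "same k")
})

test_that("zonal means average the cell centres inside the zone", {
  const <- elevation_grid(matrix(42, 5, 5), 0, 50, 10)
  expect_equal(zonal_mean(geom_rect(0, 0, 50, 50), const), 42)

  two <- elevation_grid(matrix(c(10, 20), 1, 2), 0, 10, 10)
  expect_equal(zonal_mean(geom_rect(0, 0, 20, 10), two), 15)

  set.seed(77)
  rnd <- elevation_grid(matrix(runif(100), 10, 10), 0, 100, 10)
  zone <- geom_polygon_xy(c(5, 95, 95), c(5, 5, 95))   # triangle
  idx <- which(!is.na(rnd$values), arr.ind = TRUE)
  ctr <- cell_center(rnd, idx[, 1], idx[, 2])
  inside <- geom_contains_points(zone, ctr$x, ctr$y)
  expect_equal(zonal_mean(zone, rnd), mean(rnd$values[idx][inside]))

  expect_warning(out <- zonal_mean(geom_rect(500, 500, 510, 510), rnd),
                 "no raster cell")
  expect_true(is.na(out))
})

test_that("cause tabulation reproduces known shares", {
  records <- tibble::tibble(primary_cause = c(rep("Grease", 2), "Roots",
                                              NA_character_))
  tab <- tabulate_causes(records)
  expect_equal(tab$cause[1], "Grease")
  expect_equal(tab$percentage[tab$cause == "Grease"], 50)
  expect_equal(tab$cause, c("Grease", "Roots", "Unspecified"))

  single <- tabulate_causes(tibble::tibble(primary_cause = "Debris"))
  expect_equal(single$percentage, 100)

  # percentages sum to 100 within rounding slack
  set.seed(3)
  many <- tibble::tibble(primary_cause = sample(letters[1:7], 523, TRUE))
  expect_lt(abs(sum(tabulate_causes(many)$percentage) - 100), 0.05)
})
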
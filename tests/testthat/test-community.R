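test_that("smoothing preserves constants and averages a spike over 29 cells", {
  # constant field: smoothed equals the constant to machine precision
  g <- burn_grid(matrix(7, 25, 25))
  sm <- smooth_density(g)
  expect_equal(max(abs(sm$values - 7 / 0.01)), 0, tolerance = 1e-9)

  # single 100-person cell: 10,000 people/km^2 spread over the 29 cells whose
  # centres fall within 300 m on the 100-m lattice
  z <- matrix(0, 21, 21); z[11, 11] <- 100
  sm <- smooth_density(burn_grid(z))
  expect_equal(sm$values[11, 11], 10000 / 29, tolerance = 1e-9)
  expect_equal(sum(sm$values > 0), 29)
  expect_error(smooth_density(burn_grid(z), radius_km = 0), "positive")
})

test_that("smoothed values are cellwise bounded by the raw densities", {
  set.seed(31)
  for (k in 1:100) {
    vals <- matrix(stats::rpois(400, lambda = stats::runif(1, 0, 50)), 20, 20)
    g <- burn_grid(vals)
    sm <- smooth_density(g)
    dens <- vals / 0.01
    expect_gte(min(sm$values), min(dens) - 1e-9)
    expect_lte(max(sm$values), max(dens) + 1e-9)
  }
})

test_that("buffer size keys on the 1,000-acre threshold and point geometries", {
  poly <- circle_polygon(20, 20, 1)
  expect_equal(buffer_zone(list(geometry = poly), 500)$dist_km, 10)
  expect_equal(buffer_zone(list(geometry = poly), 1500)$dist_km, 20)
  expect_equal(buffer_zone(list(geometry = poly), 1000)$dist_km, 20)  # >= is large
  expect_equal(buffer_zone(list(geometry = c(1, 1)), NA)$dist_km, 10)
  expect_error(buffer_zone(list(geometry = NULL), 100), "county-only")
  # 20-km zone strictly contains the 10-km zone
  z10 <- buffer_zone(list(geometry = poly), 500)
  z20 <- buffer_zone(list(geometry = poly), 1500)
  th <- seq(0, 2 * pi, length.out = 33)
  # the base polygon is a unit circle, so zone edges sit near 11 and 21 km
  px <- 20 + 12 * cos(th); py <- 20 + 12 * sin(th)
  expect_true(all(zone_contains(z20, px, py)))
  expect_false(any(zone_contains(z10, px, py)))
})

test_that("density exposure takes max/mean inside the zone with the >= 96 rule", {
  # 40 x 40 km grid, one town of peak 100 people/cell at (20, 20)
  world <- small_sim()$world
  w1 <- world
  w1$towns <- data.frame(x = 20, y = 20, peak = 100, sd_km = 2)
  sm <- smooth_density(generate_population_grid(w1, 2000))
  near <- buffer_zone(list(geometry = c(18, 20)), NA)       # 10-km zone
  de <- density_exposure(near, sm)
  expect_true(de$density_flag)
  expect_gt(de$max_density, 96)
  expect_gte(de$max_density, de$mean_density)

  far <- buffer_zone(list(geometry = c(38, 2)), NA)
  de2 <- density_exposure(far, sm)
  expect_false(de2$density_flag)

  # out-of-extent: zeros and a flag
  out <- buffer_zone(list(geometry = c(500, 500)), NA)
  de3 <- density_exposure(out, sm)
  expect_equal(de3$max_density, 0)
  expect_true(de3$out_of_extent)

  # exact threshold counts as a community
  g96 <- burn_grid(matrix(0.96, 30, 30))                    # 96 people/km^2
  sm96 <- smooth_density(g96)
  z <- buffer_zone(list(geometry = c(1.5, 1.5)), NA)
  expect_true(density_exposure(z, sm96)$density_flag)
})

test_that("scaling population up never lowers the density flag", {
  world <- small_sim()$world
  pop <- generate_population_grid(world, 2010)
  sm1 <- smooth_density(pop)
  pop2 <- pop; pop2$values <- pop$values * 3
  sm2 <- smooth_density(pop2)
  set.seed(77)
  for (k in 1:20) {
    z <- buffer_zone(list(geometry = c(runif(1, 5, 35), runif(1, 5, 35))), NA)
    f1 <- density_exposure(z, sm1)$density_flag
    f2 <- density_exposure(z, sm2)$density_flag
    expect_true(!f1 || f2)
  }
})

test_that("WUI overlap uses the raw geometry and ORs into the community flag", {
  n <- 60
  codes <- matrix(burnzones:::WUI_NONE, n, n)
  codes[20:30, 20:30] <- burnzones:::WUI_INTERMIX
  wui <- burn_grid(codes)
  inpoly <- cbind(x = c(2, 2.6, 2.6, 2), y = c(2, 2, 2.6, 2.6))   # over intermix
  cc <- classify_community(list(geometry = inpoly), wui, FALSE)
  expect_equal(cc$wui_class, "intermix")
  expect_true(cc$community_flag)

  outpoly <- cbind(x = c(4, 5, 5, 4), y = c(4, 4, 5, 5))
  cc2 <- classify_community(list(geometry = outpoly), wui, FALSE)
  expect_equal(cc2$wui_class, "none")
  expect_false(cc2$community_flag)
  # density alone is enough
  expect_true(classify_community(list(geometry = outpoly), wui, TRUE)$community_flag)
  # point geometry uses its containing cell
  ccp <- classify_community(list(geometry = c(2.5, 2.5)), wui, FALSE)
  expect_equal(ccp$wui_class, "intermix")
})

test_that("epoch assignment rounds to the nearest 5-year grid", {
  expect_equal(epoch_for_year(2012), 2010)
  expect_equal(epoch_for_year(2013), 2015)
  expect_equal(epoch_for_year(2020), 2020)
  expect_equal(epoch_for_year(c(2000, 2024)), c(2000, 2025))
})
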
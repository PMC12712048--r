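test_that("generation is deterministic and satisfies registry postconditions", {
  cfg <- small_world_config()
  a <- generate_truth(cfg, seed = 7)
  b <- generate_truth(cfg, seed = 7)
  expect_identical(a, b)                       # byte-identical registries
  f <- a$fires
  expect_equal(nrow(f), cfg$n_fires)
  expect_true(all(f$containment_date >= f$ignition_date))
  yr <- as.integer(format(f$ignition_date, "%Y"))
  expect_true(all(yr >= 2000 & yr <= 2025))
  # origin lies inside a listed county
  for (i in seq_len(nrow(f))) {
    own <- burnzones:::counties_touching(
      rbind(c(f$origin_x[i], f$origin_y[i]), c(f$origin_x[i] + 1e-9, f$origin_y[i]),
            c(f$origin_x[i], f$origin_y[i] + 1e-9)), a$world$counties)
    tags <- paste(a$world$counties$state[own], a$world$counties$county[own],
                  sep = ":")
    expect_true(any(tags %in% f$counties[[i]]), info = f$truth_id[i])
  }
  # perimeter area matches registered burn area within 1%
  areas <- vapply(f$perimeter, polygon_area, numeric(1))
  expect_true(all(abs(areas - acres_to_km2(f$area_acres)) /
                    acres_to_km2(f$area_acres) < 0.01))
  expect_error(generate_truth(world_config(n_fires = 0)), "positive")
})

test_that("fatality incidence matches the configured binomial rate", {
  cfg <- world_config(n_fires = 1000, extent_km = 40, n_county_side = 2,
                      n_towns = 3, p_civilian_fatality = 0.1)
  f <- generate_truth(cfg, seed = 13)$fires
  k <- sum(f$civilian_fatalities >= 1)
  sd3 <- 3 * sqrt(1000 * 0.1 * 0.9)
  expect_true(abs(k - 100) <= sd3)
})

test_that("source flavors carry era-dependent schemas", {
  sim <- small_sim(); cfg <- small_world_config()
  ics <- render_sources(sim$fires, "ics209", noise_config(), 101, cfg)
  yr <- as.integer(substr(ics$ignition_date, 1, 4))
  real <- !is.na(ics$truth_id)
  expect_true(all(is.na(ics$civilian_fatalities[real & yr <= 2013])))
  expect_true(all(!is.na(ics$total_fatalities[real])))
  expect_true(all(!is.na(ics$civilian_fatalities[real & yr >= 2014])))

  rb <- render_sources(sim$fires, "redbooks", noise_config(), 101, cfg)
  expect_true(all(rb$state == cfg$redbooks_state))
  expect_true(all(rb$area_acres >= cfg$redbooks_min_acres))
  yr_rb <- as.integer(substr(rb$ignition_date, 7, 10))
  era <- yr_rb >= 2007 & yr_rb <= 2009
  expect_true(all(!is.na(rb$combined_damaged_destroyed[era])))
  expect_true(all(is.na(rb$destroyed_structures[era])))
  expect_true(all(is.na(rb$combined_damaged_destroyed[!era])))

  fm <- render_sources(sim$fires, "fmag", noise_config(), 101, cfg)
  expect_false(any(c("civilian_fatalities", "destroyed_structures",
                     "area_acres") %in% names(fm)))
  expect_true(all(!is.na(fm$fmag_declaration_date)))
  expect_error(render_sources(sim$fires, "nope"), "arg")
})

test_that("redbooks combined field equals damaged + destroyed", {
  sim <- small_sim(); cfg <- small_world_config()
  rb <- render_sources(sim$fires, "redbooks", noise_config(intensity = 0),
                       101, cfg)
  era <- !is.na(rb$combined_damaged_destroyed)
  if (any(era)) {
    tr <- sim$fires[match(rb$truth_id[era], sim$fires$truth_id), ]
    expect_equal(rb$combined_damaged_destroyed[era],
                 tr$destroyed_structures + tr$damaged_structures)
  }
  # zero-noise identity for names and dates
  tr_all <- sim$fires[match(rb$truth_id, sim$fires$truth_id), ]
  expect_identical(rb$name, tr_all$name)
  expect_identical(as.Date(rb$ignition_date, "%m/%d/%Y"), tr_all$ignition_date)
})

test_that("perimeter flavors mirror their products' identifying fields", {
  cfg <- small_world_config()
  sim <- small_sim()
  mtbs <- render_perimeters(sim$fires, "mtbs", 101, cfg)
  cut <- ifelse(sim$fires$east[match(mtbs$truth_id, sim$fires$truth_id)],
                cfg$mtbs_min_acres_east, cfg$mtbs_min_acres_west)
  expect_true(all(mtbs$area_acres >= cut))
  expect_true(all(c("name", "shared_id", "ignition_date") %in% names(mtbs)))

  fired <- render_perimeters(sim$fires, "fired", 101, cfg)
  expect_false(any(c("name", "shared_id") %in% names(fired)))
  expect_true("containment_date" %in% names(fired))

  nifc <- render_perimeters(sim$fires, "nifc", 101, cfg)
  expect_true("year" %in% names(nifc))
  expect_false("ignition_date" %in% names(nifc))
})

test_that("a small eastern fire is kept by the eastern-size rule only", {
  sim <- small_sim(); cfg <- small_world_config()
  f <- sim$fires[1:2, ]
  f$area_acres <- c(400, 700)
  f$east <- c(TRUE, TRUE)
  f$in_mtbs <- TRUE
  out <- render_perimeters(f, "mtbs", 1, cfg)
  # 400 < 500 eastern cutoff -> excluded; 700 >= 500 -> kept
  expect_identical(out$truth_id, f$truth_id[2])
  f$east <- c(FALSE, FALSE)                    # western cutoff is 1000
  expect_equal(nrow(render_perimeters(f, "mtbs", 1, cfg)), 0L)
})

test_that("population grids are deterministic town-kernel sums", {
  world <- small_sim()$world
  g1 <- generate_population_grid(world, 2010)
  g2 <- generate_population_grid(world, 2010)
  expect_identical(g1, g2)
  expect_true(all(g1$values >= 0))
  expect_true(all(g1$values == floor(g1$values)))
  expect_error(generate_population_grid(world, 2012), "multiple of 5")
  # zero towns -> all-zero grid
  w0 <- world
  w0$towns <- world$towns[0, ]
  expect_true(all(generate_population_grid(w0, 2010)$values == 0))
  # one town: its centre cell is the grid maximum
  w1 <- world
  w1$towns <- data.frame(x = 20, y = 20, peak = 100, sd_km = 2)
  p <- generate_population_grid(w1, 2000)
  ctr <- grid_centers(p)
  peak_cell <- p$values[which.min(abs(ctr$y - 20)), which.min(abs(ctr$x - 20))]
  expect_equal(peak_cell, max(p$values))
})

test_that("rendered rows always carry a truth id joinable to the registry", {
  sc <- small_clean()
  real <- !is.na(sc$records$truth_id)
  tids <- unique(unlist(strsplit(sc$records$truth_id[real], ";")))
  expect_true(all(tids %in% sc$sim$fires$truth_id))
})
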
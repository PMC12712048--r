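# fixtures: a canonical fire + perimeter sets built from the small world
geo_fixture <- function() memo("geo_fixture", function() {
  sc <- small_clean()
  cl <- cluster_events(sc$records)
  canon <- evaluate_criteria(resolve_all(cl))
  prelim <- filter_preliminary(canon)$preliminary
  perims <- lapply(stats::setNames(nm = c("mtbs", "fired", "nifc")), function(fl)
    render_perimeters(sc$sim$fires, fl, 101, sc$cfg))
  assigned <- assign_geometries(prelim, perims, sc$sim$world$counties)
  list(sc = sc, canon = canon, prelim = prelim, perims = perims,
       assigned = assigned)
})

test_that("circle_from_point produces the right radius and area", {
  # A = pi km^2 -> radius exactly 1 km
  c1 <- circle_from_point(c(5, 5), km2_to_acres(pi))
  r <- sqrt((c1$geometry[, 1] - 5)^2 + (c1$geometry[, 2] - 5)^2)
  expect_equal(mean(r), 1, tolerance = 1e-3)
  expect_equal(polygon_area(c1$geometry), pi, tolerance = pi * 0.01)
  # 1,000 acres = 4.0469 km^2 -> r = 1.1349 km
  c2 <- circle_from_point(c(0, 0), 1000)
  expect_equal(sqrt(acres_to_km2(1000) / pi), 1.1349, tolerance = 1e-4)
  expect_equal(polygon_area(c2$geometry), acres_to_km2(1000),
               tolerance = acres_to_km2(1000) * 0.01)
  # area absent -> point geometry
  p <- circle_from_point(c(1, 2), NA)
  expect_equal(p$type, "point")
  expect_equal(unname(p$geometry), c(1, 2))
  expect_error(circle_from_point(c(0, 0), -5), "positive")
  expect_error(circle_from_point(c(0, 0), Inf), "positive")
})

test_that("tier order: shared id wins, then name/county/date, then fallbacks", {
  fx <- geo_fixture()
  a <- fx$assigned
  # every record got exactly one link method and tier counts add up
  expect_false(any(is.na(a$link_method)))
  expect_equal(nrow(a), nrow(fx$prelim))
  expect_true(all(a$link_method %in% names(burnzones:::GEOMETRY_PRECEDENCE)))

  # tier-1 fires: assigned polygon equals the truth perimeter exactly
  t1 <- which(a$link_method == "shared_id")
  for (i in t1) {
    pid <- a$perimeter_id[i]
    src <- a$geometry_source[i]
    p <- fx$perims[[src]]
    truth_poly <- p$polygon[[match(pid, p$perimeter_id)]]
    expect_identical(a$geometry[[i]], truth_poly)
    # and it is the right fire's perimeter
    expect_true(p$truth_id[match(pid, p$perimeter_id)] %in%
                  strsplit(a$truth_id[i], ";")[[1]])
  }

  # tier-1 requires the fire to carry the shared id
  expect_true(all(!is.na(a$shared_id[t1])))
})

test_that("fires without perimeter matches fall back to buffer/point/county", {
  fx <- geo_fixture()
  fire <- fx$prelim[1, , drop = FALSE]
  fire$shared_id <- NA_character_
  fire$names <- list("ZZYZX QQQQ")              # matches no perimeter name
  empty <- list(mtbs = NULL, fired = NULL, nifc = NULL)

  got <- assign_geometry(fire, empty, geolink_config())
  expect_equal(got$geometry_source, "circular_buffer")
  expect_equal(got$area_km2, acres_to_km2(fire$area_acres), tolerance = 0.01)

  fire$area_acres <- NA_real_
  got <- assign_geometry(fire, empty)
  expect_equal(got$geometry_source, "point_only")

  fire$origin_lon <- NA_real_
  got <- assign_geometry(fire, empty)
  expect_equal(got$geometry_source, "county_only")
  expect_null(got$geometry)

  fire$counties <- list(character(0))
  fire$county_states <- list(character(0))
  got <- assign_geometry(fire, empty)
  expect_equal(got$geometry_source, "rejected")
})

test_that("buffer area identity holds for all circular buffers", {
  fx <- geo_fixture()
  cb <- which(fx$assigned$link_method == "circular_buffer")
  for (i in cb) {
    a_req <- acres_to_km2(fx$assigned$area_acres[i])
    expect_lt(abs(fx$assigned$area_km2[i] - a_req) / a_req, 0.01)
  }
})

test_that("disjoint linkages merge with max counts, min/max dates, any FMAG", {
  f1 <- make_record(source_id = "m1", destroyed = 2,
                    ignition = as.Date("2012-07-01"))
  f2 <- make_record(source = "fmag", source_id = "m2", destroyed = 7,
                    ignition = as.Date("2012-06-20"))
  canon <- evaluate_criteria(resolve_all(
    cluster_events(rbind(f1, f2), match_config(jw_max = 0))))
  # force two canonical fires sharing one perimeter id
  canon <- canon[rep(1, 2), ]
  canon$fire_id <- c("WF1", "WF2")
  canon$destroyed_structures <- c(2, 7)
  canon$ignition_date <- as.Date(c("2012-07-01", "2012-06-20"))
  canon$containment_date <- as.Date(c("2012-07-10", "2012-06-25"))
  canon$fmag <- c(FALSE, TRUE)
  canon$fmag_met <- c(FALSE, TRUE)
  canon$geometry <- list(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))[rep(1, 2)]
  canon$geometry_source <- "mtbs"
  canon$link_method <- c("mtbs_name_location_date", "shared_id")
  canon$area_km2 <- 1
  canon$perimeter_id <- "MTBS-SHARED"
  merged <- merge_linked_groups(canon)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$destroyed_structures, 7)          # max
  expect_equal(merged$ignition_date, as.Date("2012-06-20"))
  expect_equal(merged$containment_date, as.Date("2012-07-10"))
  expect_true(merged$fmag)                              # any
  expect_equal(merged$link_method, "shared_id")         # tier precedence

  # distinct perimeters: nothing merges
  canon$perimeter_id <- c("P1", "P2")
  expect_equal(nrow(merge_linked_groups(canon)), 2L)
})
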
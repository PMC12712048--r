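test_that("pair_match needs county overlap, a 30-day window, and similar names", {
  a <- make_record(source_id = "a", name = "ALDER OAK",
                   ignition = as.Date("2010-06-01"))
  b <- make_record(source = "fmag", source_id = "b", name = "ALDER OAK",
                   ignition = as.Date("2010-06-11"))
  expect_true(pair_match(a, b)$match)                      # 10-day gap

  b31 <- b; b31$ignition_date <- as.Date("2010-07-02")     # 31 days
  expect_false(pair_match(a, b31)$match)
  b30 <- b; b30$ignition_date <- as.Date("2010-07-01")     # exactly 30
  expect_true(pair_match(a, b30)$match)

  bc <- b; bc$counties <- list("BASALT")                   # disjoint county
  expect_false(pair_match(a, bc)$match)

  bn <- b; bn$clean_name <- "OCEAN OAK"
  d <- pair_match(a, bn)
  expect_false(d$match)
  expect_gt(d$evidence$name_distance, 0.25)

  # RIVER vs OCEAN alone: distance 0.5333 > 0.25
  r <- make_record(source_id = "r", name = "RIVER")
  o <- make_record(source = "fmag", source_id = "o", name = "OCEAN")
  expect_false(pair_match(r, o)$match)
  expect_equal(pair_match(r, o)$evidence$name_distance, 0.53333,
               tolerance = 1e-4)

  # symmetry
  expect_identical(pair_match(a, b)$match, pair_match(b, a)$match)
})

test_that("missing dates fall back to declaration date, else are waived by config", {
  a <- make_record(source_id = "a", ignition = as.Date("2010-06-01"))
  fm <- make_record(source = "fmag", source_id = "f", ignition = as.Date(NA),
                    declaration = as.Date("2010-06-05"))
  fm$year <- 2010L
  expect_true(pair_match(a, fm)$match)
  fm$fmag_declaration_date <- as.Date("2011-06-05")
  expect_false(pair_match(a, fm)$match)
  fm$fmag_declaration_date <- as.Date(NA)
  expect_true(pair_match(a, fm, match_config(waive_missing_date = TRUE))$match)
  expect_false(pair_match(a, fm, match_config(waive_missing_date = FALSE))$match)
})

test_that("clusters are connected components and row-order invariant", {
  # A-B and B-C edges but no direct A-C edge (disjoint counties): transitive
  a <- make_record(source_id = "a", county = "ALDERWOOD")
  b <- make_record(source = "redbooks", source_id = "b")
  b$counties <- list(c("ALDERWOOD", "BASALT"))
  b$states <- list(c("CA", "CA"))
  c <- make_record(source = "fmag", source_id = "c", county = "BASALT")
  stopifnot(!pair_match(a, c)$match, pair_match(a, b)$match,
            pair_match(b, c)$match)
  cl <- cluster_events(rbind(a, b, c))
  expect_equal(length(cl$clusters), 1L)
  expect_equal(sort(cl$records$source_id), c("a", "b", "c"))

  # no qualifying pairs -> three singletons
  z <- rbind(make_record(source_id = "x", name = "GRANITE ELK"),
             make_record(source_id = "y", name = "WILLOW TROUT",
                         ignition = as.Date("2011-01-01")),
             make_record(source_id = "z", name = "PUMICE HAWK",
                         ignition = as.Date("2012-01-01")))
  expect_equal(length(cluster_events(z)$clusters), 3L)

  # permuting input rows leaves the partition unchanged
  p1 <- cluster_events(rbind(a, b, c))$records
  p2 <- cluster_events(rbind(c, a, b))$records
  expect_identical(p1[order(p1$source_id), c("source_id", "cluster")],
                   p2[order(p2$source_id), c("source_id", "cluster")])
})

test_that("linkage recovers generator truth exactly at default noise", {
  sc <- small_clean()
  cl <- cluster_events(sc$records)
  labels <- truth_unit_labels(cl$records, sc$sim$fires)
  expect_equal(ari(cl$records$cluster, labels), 1.0)
})

test_that("conflict resolution follows the Redbooks-wins precedence", {
  ics <- make_record(source_id = "i", destroyed = 5, civilian = 2,
                     ignition = as.Date("2015-06-03"))
  rb <- make_record(source = "redbooks", source_id = "r", destroyed = 3,
                    civilian = 1, ignition = as.Date("2015-06-05"))
  out <- resolve_cluster(rbind(ics, rb))
  expect_equal(out$destroyed_structures, 3)       # Redbooks value wins
  expect_equal(out$civilian_fatalities, 1)
  expect_equal(out$ignition_date, as.Date("2015-06-05"))  # Redbooks date wins

  # no Redbooks: earliest ignition across ICS-209/FMAG
  fm <- make_record(source = "fmag", source_id = "f",
                    ignition = as.Date("2015-06-01"))
  out2 <- resolve_cluster(rbind(ics, fm))
  expect_equal(out2$ignition_date, as.Date("2015-06-01"))
  expect_equal(out2$destroyed_structures, 5)
  expect_true(out2$fmag)

  # without Redbooks, cross-source conflicts resolve to the maximum
  m <- rbind(make_record(source_id = "1", destroyed = 2),
             make_record(source = "fmag", source_id = "2", destroyed = 7))
  expect_equal(resolve_cluster(m)$destroyed_structures, 7)
  expect_error(resolve_cluster(make_record()[0, ]), "empty")
})

test_that("complex members aggregate by sum within a source (switchable to max)", {
  m <- rbind(make_record(source = "redbooks", source_id = "r1", destroyed = 2),
             make_record(source = "redbooks", source_id = "r2", destroyed = 4),
             make_record(source = "redbooks", source_id = "r2", destroyed = 4))
  expect_equal(resolve_cluster(m)$destroyed_structures, 6)  # dedup r2, then sum
  expect_equal(resolve_cluster(m, match_config(complex_mode = "max"))$destroyed_structures, 4)
})

test_that("resolution is re-derivable from stored members", {
  sc <- small_clean()
  cl <- cluster_events(sc$records)
  canon <- resolve_all(cl)
  for (i in sample(nrow(canon), min(10, nrow(canon)))) {
    ix <- cl$clusters[[i]]
    re <- resolve_cluster(cl$records[ix, , drop = FALSE])
    for (col in c("civilian_fatalities", "destroyed_structures",
                  "area_acres", "fmag")) {
      expect_identical(re[[col]], canon[[col]][i], info = col)
    }
    expect_identical(re$ignition_date, canon$ignition_date[i])
  }
})
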
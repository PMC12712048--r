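test_that("percent shares round half-up to one decimal", {
  expect_equal(percent_share(6212, 6871), 90.4)
  expect_equal(percent_share(344, 407), 84.5)
  expect_equal(percent_share(0, 10), 0.0)
  expect_equal(percent_share(1, 3), 33.3)
  expect_equal(percent_share(5, 8), 62.5)
  expect_equal(percent_share(1, 16), 6.3)      # 6.25 rounds half-up
  expect_error(percent_share(1, 0), "positive")
})

test_that("Mann-Kendall handles monotone series and small worked examples", {
  up <- mann_kendall(1:5)
  expect_equal(up$S, 10L); expect_equal(up$tau, 1)
  dn <- mann_kendall(5:1)
  expect_equal(dn$tau, -1)
  ex <- mann_kendall(c(1, 3, 2, 4))
  expect_equal(ex$S, 4L)
  expect_equal(ex$tau, 0.6667, tolerance = 1e-4)
  expect_error(mann_kendall(c(1, 2)), "at least 3")
  # all ties: S = 0, tau = 0, p = 1-ish
  tied <- mann_kendall(rep(2, 5))
  expect_equal(tied$S, 0L); expect_equal(tied$tau, 0)
})

test_that("Mann-Kendall agrees with the all-pairs oracle exhaustively (n <= 8)", {
  for (n in 3:8) {
    grid <- as.matrix(expand.grid(rep(list(0:2), n)))
    for (r in seq_len(nrow(grid))) {
      x <- grid[r, ]
      got <- mann_kendall(x)
      want <- mk_oracle(x)
      if (got$S != want$S || abs(got$tau - want$tau) > 1e-12 ||
          abs(got$var_S - want$var_S) > 1e-9) {
        fail(sprintf("mismatch at series [%s]", paste(x, collapse = ",")))
      }
    }
    succeed()
  }
})

test_that("exact p-values match full enumeration for tie-free series", {
  # enumeration oracle over all permutations of ranks
  exact_oracle <- function(x) {
    n <- length(x)
    perms <- burnzones_perms(n)
    S_obs <- mk_oracle(x)$S
    S_all <- apply(perms, 1, function(p) mk_oracle(p)$S)
    mean(abs(S_all) >= abs(S_obs))
  }
  burnzones_perms <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- burnzones_perms(n - 1)
    do.call(rbind, lapply(1:n, function(k)
      cbind(k, sub + (sub >= k))))
  }
  for (x in list(c(1, 3, 2, 4), c(2, 1, 4, 3, 5), c(1, 2, 3, 4, 5, 6))) {
    got <- mann_kendall(x, method = "exact")
    expect_equal(got$p, exact_oracle(x), tolerance = 1e-12,
                 info = paste(x, collapse = ","))
  }
  expect_error(mann_kendall(c(1, 1, 2), method = "exact"), "tie-free")
})

test_that("summary tables count multi-state records once per state", {
  rec <- data.frame(year = c(2001, 2001, 2005))
  rec$states <- list("CA", c("CA", "NV"), "NV")
  rec$fatality_met <- c(TRUE, FALSE, FALSE)
  rec$structure_met <- c(FALSE, TRUE, TRUE)
  rec$fmag_met <- c(FALSE, FALSE, TRUE)
  rec$wui_class <- c("intermix", "none", NA)
  s <- summarize_counts(rec)
  expect_equal(s$by_year$n[s$by_year$year == 2001], 2)
  expect_equal(s$by_state$n[s$by_state$state == "CA"], 2)
  expect_equal(s$by_state$n[s$by_state$state == "NV"], 2)
  expect_equal(sum(s$by_state$n), 4)           # 3 records + 1 multistate dup
  expect_equal(s$by_criterion$n, c(1, 2, 1))
})

test_that("GeoJSON output round-trips records, null geometry included", {
  fx <- memo("pipe_small", function()
    run_pipeline(pipeline_config(world = small_world_config(), seed = 101)))
  path <- file.path(tempdir(), "round.geojson")
  write_outputs(fx$records, path, fx$world$frame)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(tempdir(), "round_data_dictionary.md")))
  back <- read_disasters(path, fx$world$frame)
  expect_equal(nrow(back), nrow(fx$records))
  expect_identical(back$fire_id, fx$records$fire_id)
  expect_equal(back$destroyed_structures, fx$records$destroyed_structures)
  expect_identical(back$ignition_date, fx$records$ignition_date)
  expect_identical(back$wui_class, fx$records$wui_class)
  expect_identical(back$community_flag, fx$records$community_flag)
  expect_identical(lapply(back$names, sort), lapply(fx$records$names, sort))
  # geometries survive the lon/lat round trip
  has_geom <- !vapply(fx$records$geometry, is.null, logical(1))
  for (i in which(has_geom)[1:min(5, sum(has_geom))]) {
    g0 <- fx$records$geometry[[i]]; g1 <- back$geometry[[i]]
    if (is.null(dim(g0))) {
      expect_equal(unname(g1), unname(g0), tolerance = 1e-6)
    } else {
      expect_equal(unname(g1), unname(g0[, 1:2]), tolerance = 1e-6)
    }
  }
  # county-only records -> null geometry but states retained
  co <- which(fx$records$geometry_source == "county_only")
  if (length(co)) {
    expect_null(back$geometry[[co[1]]])
    expect_false(any(is.na(back$states[[co[1]]])))
  }
})

test_that("ascii grid files round-trip", {
  g <- burn_grid(matrix(runif(120), 10, 12), cell = 0.5, x0 = 3, y0 = -2)
  p <- file.path(tempdir(), "g.asc")
  write_grid_asc(g, p)
  g2 <- read_grid_asc(p)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$cell, g$cell)
  expect_equal(g2$x0, g$x0)
})
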
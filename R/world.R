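# Synthetic fire world.
#
# Generates a reproducible ground-truth registry of wildfires over a planar
# equal-area extent (counties, towns, vegetation and housing grids), then
# renders it into the three noisy incident-table flavors (ICS-209-like,
# Redbooks-like, FMAG-like) and three perimeter-set flavors (MTBS-like,
# FIRED-like, NIFC-like) that the downstream pipeline consumes.  Every
# rendered row carries a hidden `truth_id` used only by tests.

FIRE_WORDS <- c(
  "ALDER", "ASPEN", "BADGER", "BASIN", "BEAR", "BIRCH", "BOBCAT", "BOULDER",
  "CAMP", "CEDAR", "CINDER", "CLOVER", "CONDOR", "COYOTE", "DEER", "DIXIE",
  "EAGLE", "ELK", "EMBER", "FALCON", "FLINT", "GRANITE", "HAWK", "HOLLOW",
  "IRONWOOD", "JUNIPER", "KESTREL", "LARKSPUR", "LUPINE", "MANZANITA",
  "MAPLE", "MESA", "MOOSE", "NUGGET", "OAK", "OSPREY", "OTTER", "OWL",
  "PINE", "PUMICE", "QUAIL", "RAVEN", "REDWOOD", "SABLE", "SAGE", "SEQUOIA",
  "SIERRA", "SPRUCE", "SUMAC", "TAMARACK", "THISTLE", "TROUT", "TULE",
  "VERBENA", "WALNUT", "WILLOW", "WOLF", "YARROW", "YUCCA", "ZEPHYR",
  "ACORN", "AGATE", "AMBER", "ANTLER", "ARROYO", "AVALON", "AZTEC",
  "BALSAM", "BARLEY", "BEACON", "BELLOW", "BISON", "BLUFF", "BRACKEN",
  "BRIDGER", "BRONCO", "BUCKEYE", "BURROW", "CACTUS", "CALICO", "CARIBOU",
  "CASCADE", "CHERT", "CHICORY", "CLIFF", "COBALT", "COLUMBINE", "COMET",
  "CORAL", "COTTONWOOD", "COUGAR", "CRATER", "CRICKET", "CUMULUS", "CYPRESS",
  "DAGGER", "DELTA", "DOGWOOD", "DOLOMITE", "DRIFTER", "DUSTDEVIL", "EBONY",
  "ECHO", "ELDER", "ERMINE", "FENNEL", "FERRET", "FIDDLE", "FIREWEED",
  "FJORD", "FOSSIL", "FOXTAIL", "GALENA", "GARNET", "GECKO", "GINKGO",
  "GLACIER", "GOPHER", "GOSHAWK", "GRIFFIN", "GROUSE", "GYPSUM", "HACKBERRY",
  "HALCYON", "HARRIER", "HEMLOCK", "HERON", "HICKORY", "HONEYBEE", "HORIZON",
  "IBEX", "INDIGO", "INKWELL", "JACKRABBIT", "JAGUAR", "JASPER", "JAYBIRD",
  "JERICHO", "JONQUIL", "KELP", "KINGBIRD", "KNOLL", "KODIAK", "LAGOON",
  "LANTERN", "LAUREL", "LICHEN", "LIMESTONE", "LOCUST", "LYNX", "MADRONE",
  "MAGPIE", "MALLARD", "MAMMOTH", "MARBLE", "MARIGOLD", "MARMOT", "MERLIN",
  "MILKWEED", "MINNOW", "MIRAGE", "MOJAVE", "MONARCH", "MULBERRY", "MUSTANG",
  "NARWHAL", "NECTAR", "NETTLE", "NIMBUS", "NUTMEG", "OBSIDIAN", "OCELOT",
  "OLIVE", "ONYX", "OPAL", "ORIOLE", "OXBOW", "PADDOCK", "PALOMINO",
  "PANTHER", "PEBBLE", "PELICAN", "PEREGRINE", "PERSIMMON", "PEWTER",
  "PHEASANT", "PINNACLE", "PLOVER", "POPPY", "PORCUPINE", "PRIMROSE",
  "PRONGHORN", "QUARTZ", "QUICKSILVER", "QUIVER", "RACCOON", "RAMBLER",
  "RATTLER", "REDTAIL", "ROADRUNNER", "ROSEWOOD", "RUSSET", "SADDLE",
  "SALAMANDER", "SANDPIPER", "SAPPHIRE", "SASSAFRAS", "SAWTOOTH", "SCORPION",
  "SHALE", "SIDEWINDER", "SILVERADO", "SKYLARK", "SNOWBERRY", "SOLSTICE",
  "SPARROW", "STARLING", "STEEPLE", "STIRRUP", "SUNDOWN", "SWALLOWTAIL",
  "SYCAMORE", "TALON", "TANAGER", "TARPON", "TEMPEST", "THRUSH", "TIMBERLINE",
  "TOPAZ", "TORTOISE", "TUMBLEWEED", "TUNDRA", "TURQUOISE", "TWILIGHT",
  "UMBER", "VAQUERO", "VERMILION", "VOLE", "VULTURE", "WAGTAIL", "WARBLER",
  "WATERCRESS", "WEASEL", "WHETSTONE", "WHIPPOORWILL", "WISTERIA",
  "WOLVERINE", "WOODRAT", "WREN", "XERIC", "YEARLING", "ZINNIA")

COUNTY_NAMES <- c(
  "LOS ANGELES", "ALDERWOOD", "BASALT", "CHAPARRAL", "DUNMORE", "ELKHORN",
  "FOXGLOVE", "GREENSTONE", "HALCYON", "IRONBARK", "JADEWATER", "KINGFISHER",
  "LARCHMONT", "MIDLAND", "NORTHGATE", "OVERLOOK")

#' Configuration for the synthetic fire world
#'
#' Defaults describe the stated world used throughout the tests: a 120 x 120
#' km equal-area extent split into two states and a 4 x 4 county grid, 100-m
#' grids, towns as isotropic Gaussian population kernels, fires spanning
#' 2000-2025 with era-dependent source coverage.
#'
#' @param n_fires number of truth fires.
#' @param extent_km width/height of the square extent in km.
#' @param n_county_side counties per side (n^2 rectangular counties).
#' @param states two state codes; the extent is split into vertical bands.
#' @param redbooks_state state covered by the Redbooks-like source.
#' @param n_towns number of population kernels.
#' @param cell_km grid cell edge (default 0.1 km = 100 m).
#' @param year_range ignition-year range (within 2000-2025).
#' @param p_civilian_fatality probability a fire kills >= 1 civilian.
#' @param p_responder_fatality probability of >= 1 responder death.
#' @param p_destroyed probability a fire destroys >= 1 structure.
#' @param p_damaged probability a fire damages >= 1 structure.
#' @param p_fmag probability of a federal fire-assistance declaration.
#' @param complex_fraction fraction of fires grouped into complexes.
#' @param p_ics209,p_mtbs,p_fired,p_nifc per-source presence probabilities.
#' @param p_shared_id probability a fire carries the shared interagency id.
#' @param p_east probability a fire is tagged "eastern" for the MTBS size rule.
#' @param mtbs_min_acres_west,mtbs_min_acres_east MTBS inclusion cutoffs.
#' @param redbooks_min_acres Redbooks large-fire threshold (acres).
#' @param area_meanlog,area_sdlog lognormal burn-area parameters (acres).
#' @param nonfire_rows,pre2000_rows junk rows injected into the ICS-209 flavor
#'   to exercise cleaning.
#' @return a list of class `world_config`.
#' @export
world_config <- function(n_fires = 200,
                         extent_km = 120,
                         n_county_side = 4,
                         states = c("CA", "NV"),
                         redbooks_state = "CA",
                         n_towns = 12,
                         cell_km = 0.1,
                         year_range = c(2000, 2025),
                         p_civilian_fatality = 0.1,
                         p_responder_fatality = 0.05,
                         p_destroyed = 0.35,
                         p_damaged = 0.30,
                         p_fmag = 0.12,
                         complex_fraction = 0.15,
                         p_ics209 = 0.95,
                         p_mtbs = 0.8,
                         p_fired = 0.7,
                         p_nifc = 0.6,
                         p_shared_id = 0.5,
                         p_east = 0.3,
                         mtbs_min_acres_west = 1000,
                         mtbs_min_acres_east = 500,
                         redbooks_min_acres = 300,
                         area_meanlog = log(600),
                         area_sdlog = 1.4,
                         nonfire_rows = 2,
                         pre2000_rows = 2) {
  cfg <- as.list(environment())
  if (cfg$n_fires <= 0) stop("n_fires must be positive")
  if (cfg$extent_km <= 0) stop("extent must be non-empty")
  stopifnot(length(states) == 2L, year_range[1] >= 2000, year_range[2] <= 2025)
  class(cfg) <- "world_config"
  cfg
}

# deterministic sub-seed below 2^31 for a named stage
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 48271 + h) %% 2147483647
}

make_counties <- function(cfg) {
  k <- cfg$n_county_side
  w <- cfg$extent_km / k
  out <- vector("list", k * k)
  idx <- 1L
  for (ix in seq_len(k)) {
    for (iy in seq_len(k)) {
      x0 <- (ix - 1) * w; y0 <- (iy - 1) * w
      state <- if (ix <= k / 2) cfg$states[1] else cfg$states[2]
      poly <- cbind(x = c(x0, x0 + w, x0 + w, x0),
                    y = c(y0, y0, y0 + w, y0 + w))
      out[[idx]] <- list(state = state,
                         county = COUNTY_NAMES[(idx - 1L) %% length(COUNTY_NAMES) + 1L],
                         polygon = poly)
      idx <- idx + 1L
    }
  }
  df <- data.frame(state = vapply(out, `[[`, "", "state"),
                   county = vapply(out, `[[`, "", "county"),
                   stringsAsFactors = FALSE)
  df$polygon <- lapply(out, `[[`, "polygon")
  df
}

#' Gazetteer of the synthetic world's counties
#' @param world a `synthetic_world`.
#' @return a [gazetteer()] with the "LA"-style alias enabled for the state
#'   that contains a LOS ANGELES county.
#' @export
world_gazetteer <- function(world) {
  cts <- world$counties
  al <- cts[cts$county == "LOS ANGELES", c("state", "county")]
  aliases <- if (nrow(al)) {
    data.frame(state = al$state[1], alias = c("LA", "LA CO"),
               canonical = "LOS ANGELES")
  } else NULL
  gazetteer(cts[c("state", "county")], aliases = aliases)
}

# star-shaped simple polygon around (cx, cy) scaled to the target area exactly
star_perimeter <- function(cx, cy, area_km2, n_vertices = 24L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- 1 + 0.35 * stats::runif(n_vertices, -1, 1)
  poly <- cbind(x = r * cos(th), y = r * sin(th))
  s <- sqrt(area_km2 / polygon_area(poly))
  cbind(x = cx + s * poly[, 1], y = cy + s * poly[, 2])
}

# counties whose rectangle touches the polygon (vertex-in-rect, corner-in-poly
# or boundary distance zero-ish)
counties_touching <- function(poly, counties, pad_km = 0) {
  hits <- logical(nrow(counties))
  for (i in seq_len(nrow(counties))) {
    r <- counties$polygon[[i]]
    if (any(points_in_polygon(poly[, 1], poly[, 2], r))) { hits[i] <- TRUE; next }
    if (any(points_in_polygon(r[, 1], r[, 2], poly))) { hits[i] <- TRUE; next }
    d <- min(dist_points_to_polygon(r[, 1], r[, 2], poly),
             dist_points_to_polygon(poly[, 1], poly[, 2], r))
    hits[i] <- d <= pad_km + 1e-9
  }
  which(hits)
}

#' Generate the synthetic world and its ground-truth fire registry
#'
#' Deterministic for a fixed (config, seed).  Fire origins are sampled inside
#' counties, perimeters are star-shaped simple polygons whose planar area
#' equals the registered burn area, and truth names are drawn so that distinct
#' incidents are mutually farther than 0.3 in Jaro-Winkler distance (real
#' incident names are administratively distinct; this keeps ground truth
#' unambiguous).
#'
#' @param config a [world_config()].
#' @param seed integer seed.
#' @return list with elements `world` (counties, towns, vegetation and housing
#'   grids, frame) and `fires` (truth registry data.frame with list-columns
#'   `perimeter` and `counties`).
#' @export
generate_truth <- function(config = world_config(), seed = 1) {
  cfg <- config
  set.seed(sub_seed(seed, "world"))
  ext <- cfg$extent_km
  counties <- make_counties(cfg)

  towns <- data.frame(
    x = stats::runif(cfg$n_towns, 0.08 * ext, 0.92 * ext),
    y = stats::runif(cfg$n_towns, 0.08 * ext, 0.92 * ext),
    peak = stats::rlnorm(cfg$n_towns, log(60), 0.8),     # people per 100-m cell
    sd_km = stats::runif(cfg$n_towns, 1, 3.5))

  ncell <- round(ext / cfg$cell_km)
  frame <- burn_frame()
  housing <- matrix(0, ncell, ncell)
  ctr <- (seq_len(ncell) - 0.5) * cfg$cell_km
  for (t in seq_len(nrow(towns))) {
    ix <- which(abs(ctr - towns$x[t]) <= 4 * towns$sd_km[t])
    iy <- which(abs(ctr - towns$y[t]) <= 4 * towns$sd_km[t])
    if (!length(ix) || !length(iy)) next
    gx <- exp(-((ctr[ix] - towns$x[t])^2) / (2 * towns$sd_km[t]^2))
    gy <- exp(-((ctr[iy] - towns$y[t])^2) / (2 * towns$sd_km[t]^2))
    # peak people/cell -> peak houses/km^2 at ~2.6 people per household
    peak_h <- towns$peak[t] * 100 / 2.6
    housing[iy, ix] <- housing[iy, ix] + peak_h * outer(gy, gx)
  }
  vegetation <- 0.9 - 0.8 * housing / (housing + 30)
  # mild large-scale variation so vegetation patches have structure
  vx <- outer(sin(ctr / ext * 3 * pi), cos(ctr / ext * 2 * pi))
  vegetation <- pmin(pmax(vegetation + 0.05 * t(vx), 0), 1)

  world <- structure(list(
    extent_km = ext, counties = counties, towns = towns,
    vegetation = burn_grid(vegetation, cell = cfg$cell_km, frame = frame),
    housing = burn_grid(housing, cell = cfg$cell_km, frame = frame),
    frame = frame, cell_km = cfg$cell_km, config = cfg, seed = seed),
    class = "synthetic_world")

  set.seed(sub_seed(seed, "fires"))
  n <- cfg$n_fires
  # unique two-word names, mutually separated in JW distance
  combos <- expand.grid(a = FIRE_WORDS, b = FIRE_WORDS, stringsAsFactors = FALSE)
  combos <- combos[combos$a != combos$b, ]
  combos <- combos[sample(nrow(combos)), ]
  # one name per distinct leading word guarantees pairwise JW distance > 0.3;
  # worlds larger than the vocabulary fill with unique (but less separated)
  # word pairs, which only matters for ground-truth-purity tests
  names_out <- character(0)
  used_first <- character(0)
  rest <- character(0)
  for (i in seq_len(nrow(combos))) {
    cand <- paste(combos$a[i], combos$b[i])
    if (!(combos$a[i] %in% used_first) &&
        (!length(names_out) || min(jw_distance(cand, names_out)) > 0.3)) {
      names_out <- c(names_out, cand)
      used_first <- c(used_first, combos$a[i])
    } else {
      rest <- c(rest, cand)
    }
    if (length(names_out) >= n) break
  }
  if (length(names_out) < n) names_out <- c(names_out, rest)[seq_len(n)]

  n_complex <- floor(cfg$complex_fraction * n / 2)  # complexes of ~2-3 fires
  complex_id <- rep(NA_character_, n)
  fire_name <- names_out
  pos <- 1L
  for (ci in seq_len(n_complex)) {
    sz <- sample(2:3, 1)
    if (pos + sz - 1L > n) break
    idx <- pos:(pos + sz - 1L)
    complex_id[idx] <- sprintf("C%02d", ci)
    fire_name[idx] <- paste(names_out[pos], "COMPLEX")
    pos <- pos + sz
  }

  county_idx <- sample(nrow(counties), n, replace = TRUE)
  # complex member fires burn next to each other: same county as the lead fire
  for (i in seq_len(n)) {
    if (!is.na(complex_id[i])) {
      lead <- match(complex_id[i], complex_id)
      county_idx[i] <- county_idx[lead]
    }
  }
  area_acres <- stats::rlnorm(n, cfg$area_meanlog, cfg$area_sdlog)
  area_acres <- pmin(area_acres, 60000)  # keep perimeters inside the extent

  origin <- matrix(NA_real_, n, 2)
  perimeter <- vector("list", n)
  counties_list <- vector("list", n)
  states_chr <- character(n)
  for (i in seq_len(n)) {
    r <- counties$polygon[[county_idx[i]]]
    rad <- sqrt(acres_to_km2(area_acres[i]) / pi)
    lo_x <- min(r[, 1]) + 0.1; hi_x <- max(r[, 1]) - 0.1
    lo_y <- min(r[, 2]) + 0.1; hi_y <- max(r[, 2]) - 0.1
    origin[i, ] <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
    if (!is.na(complex_id[i])) {
      lead <- match(complex_id[i], complex_id)
      if (lead < i) {                    # cluster around the lead fire
        origin[i, ] <- origin[lead, ] + stats::runif(2, -1.5, 1.5)
      }
    }
    # clamp so the whole perimeter stays inside the extent
    m <- 1.5 * rad
    origin[i, 1] <- min(max(origin[i, 1], m), ext - m)
    origin[i, 2] <- min(max(origin[i, 2], m), ext - m)
    perimeter[[i]] <- star_perimeter(origin[i, 1], origin[i, 2],
                                     acres_to_km2(area_acres[i]))
    hit <- counties_touching(perimeter[[i]], counties)
    # the origin's county is always listed
    oc <- counties_touching(rbind(origin[i, ], origin[i, ] + 1e-6,
                                  origin[i, ] + c(1e-6, 0)), counties)
    hit <- sort(union(hit, oc))
    counties_list[[i]] <- paste(counties$state[hit], counties$county[hit], sep = ":")
    states_chr[i] <- paste(unique(counties$state[hit]), collapse = ";")
  }

  d0 <- as.Date(sprintf("%d-01-01", cfg$year_range[1]))
  d1 <- as.Date(sprintf("%d-12-31", cfg$year_range[2]))
  if (cfg$year_range[2] == 2025) d1 <- as.Date("2025-06-15")
  ignition <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L
  for (i in seq_len(n)) {                # complex members ignite together
    if (!is.na(complex_id[i])) {
      lead <- match(complex_id[i], complex_id)
      if (lead < i) ignition[i] <- ignition[lead] + sample(0:10, 1)
    }
  }
  duration <- 1L + stats::rpois(n, 12)
  containment <- ignition + duration

  civ <- stats::rbinom(n, 1, cfg$p_civilian_fatality) * (1L + stats::rpois(n, 1))
  resp <- stats::rbinom(n, 1, cfg$p_responder_fatality) * (1L + stats::rpois(n, 0.5))
  destr <- stats::rbinom(n, 1, cfg$p_destroyed) *
    pmax(1, round(stats::rlnorm(n, log(4), 1.3)))
  dam <- stats::rbinom(n, 1, cfg$p_damaged) *
    pmax(1, round(stats::rlnorm(n, log(3), 1.0)))
  fmag <- stats::rbinom(n, 1, cfg$p_fmag) == 1

  fires <- data.frame(
    truth_id = sprintf("T%04d", seq_len(n)),
    name = fire_name,
    complex_id = complex_id,
    state = states_chr,
    area_acres = area_acres,
    civilian_fatalities = civ,
    responder_fatalities = resp,
    destroyed_structures = destr,
    damaged_structures = dam,
    fmag = fmag,
    east = stats::rbinom(n, 1, cfg$p_east) == 1,
    in_ics209 = stats::rbinom(n, 1, cfg$p_ics209) == 1,
    in_mtbs = stats::rbinom(n, 1, cfg$p_mtbs) == 1,
    in_fired = stats::rbinom(n, 1, cfg$p_fired) == 1,
    in_nifc = stats::rbinom(n, 1, cfg$p_nifc) == 1,
    has_shared_id = stats::rbinom(n, 1, cfg$p_shared_id) == 1,
    stringsAsFactors = FALSE)
  fires$ignition_date <- ignition
  fires$containment_date <- containment
  fires$origin_x <- origin[, 1]
  fires$origin_y <- origin[, 2]
  fires$perimeter <- perimeter
  fires$counties <- counties_list
  fires$shared_id <- ifelse(fires$has_shared_id,
                            sprintf("IRW-%04d", seq_len(n)), NA_character_)
  # complexes share one reporting unit in complex-level sources
  fires$in_ics209[!is.na(fires$complex_id)] <- TRUE

  list(world = world, fires = fires)
}

#' Perturbation settings for source rendering
#'
#' Defaults keep noise strictly inside the linkage tolerances: at most one
#' in-token character substitution per name (Jaro-Winkler displacement well
#' under 0.2 for the two-word names generated here) and date jitter of at most
#' 7 days per source (cross-source gap <= 14 < 30 days); counties are
#' unperturbed.
#'
#' @param name_edit_prob probability a rendered name receives one character
#'   substitution (never the first character of a token).
#' @param date_jitter_days maximum +/- jitter applied to dates, in days.
#' @param county_drop_prob probability a multi-county row drops one county.
#' @param intensity overall multiplier; 0 renders sources exactly equal to
#'   truth (zero-noise identity).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(name_edit_prob = 0.3, date_jitter_days = 7,
                         county_drop_prob = 0, intensity = 1) {
  structure(list(name_edit_prob = name_edit_prob * intensity,
                 date_jitter_days = as.integer(round(date_jitter_days * intensity)),
                 county_drop_prob = county_drop_prob * intensity),
            class = "noise_config")
}

perturb_name <- function(name, prob) {
  out <- name
  for (i in seq_along(out)) {
    if (stats::runif(1) >= prob) next
    toks <- strsplit(out[i], " ", fixed = TRUE)[[1]]
    lens <- nchar(toks)
    ok <- which(lens >= 4)     # only edit long tokens, never the first char
    if (!length(ok)) next
    t <- ok[sample.int(length(ok), 1)]
    pos <- sample(2:(lens[t] - 1), 1)
    ch <- sample(setdiff(LETTERS, substr(toks[t], pos, pos)), 1)
    substr(toks[t], pos, pos) <- ch
    out[i] <- paste(toks, collapse = " ")
  }
  out
}

jitter_dates <- function(d, max_days) {
  if (max_days <= 0) return(d)
  d + sample(seq(-max_days, max_days), length(d), replace = TRUE)
}

split_counties <- function(tags) {
  # "ST:COUNTY" tags -> list(states=..., counties=...)
  parts <- strsplit(tags, ":", fixed = TRUE)
  list(states = unique(vapply(parts, `[`, "", 1)),
       counties = unique(vapply(parts, `[`, "", 2)))
}

# complex-level reporting units: one row per complex, one per singleton fire
reporting_units <- function(fires) {
  unit <- ifelse(is.na(fires$complex_id), fires$truth_id, fires$complex_id)
  split(seq_len(nrow(fires)), unit)
}

#' Render the truth registry into a noisy source-flavored table
#'
#' @param truth the `fires` registry from [generate_truth()].
#' @param flavor one of `"ics209"`, `"redbooks"`, `"fmag"`.
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param config the [world_config()] used to generate the truth (for the
#'   Redbooks state and large-fire threshold).
#' @return data.frame in the flavor's schema (dates as character in the
#'   flavor's dialect; hidden `truth_id` column for tests only).
#' @export
render_sources <- function(truth, flavor = c("ics209", "redbooks", "fmag"),
                           noise = noise_config(), seed = 1,
                           config = world_config()) {
  flavor <- match.arg(flavor)
  set.seed(sub_seed(seed, paste0("render_", flavor)))
  cfg <- config

  # jitter once up front so era-dependent schema rules key on rendered dates
  truth$ignition_date <- jitter_dates(truth$ignition_date, noise$date_jitter_days)
  truth$containment_date <- pmax(
    jitter_dates(truth$containment_date, noise$date_jitter_days),
    truth$ignition_date)

  if (flavor == "ics209") {
    units <- reporting_units(truth[truth$in_ics209, , drop = FALSE])
    rows <- lapply(units, function(ix) {
      f <- truth[truth$in_ics209, , drop = FALSE][ix, , drop = FALSE]
      sc <- split_counties(unique(unlist(f$counties)))
      yr <- as.integer(format(min(f$ignition_date), "%Y"))
      civ <- sum(f$civilian_fatalities)
      tot <- civ + sum(f$responder_fatalities)
      data.frame(
        source = "ics209",
        source_id = paste0("ICS-", f$truth_id[1]),
        name = f$name[1],
        state = paste(sc$states, collapse = ";"),
        counties = paste(sc$counties, collapse = ";"),
        ignition_date = format(min(f$ignition_date), "%Y-%m-%d"),
        containment_date = format(max(f$containment_date), "%Y-%m-%d"),
        # the 2000-2013 schemas did not break out civilian deaths
        civilian_fatalities = if (yr <= 2013) NA_integer_ else civ,
        total_fatalities = tot,
        destroyed_structures = sum(f$destroyed_structures),
        damaged_structures = sum(f$damaged_structures),
        origin_lon = planar_to_lonlat(c(f$origin_x[1], f$origin_y[1]),
                                      burn_frame())[1, 1],
        origin_lat = planar_to_lonlat(c(f$origin_x[1], f$origin_y[1]),
                                      burn_frame())[1, 2],
        area_acres = sum(f$area_acres),
        shared_id = if (any(f$has_shared_id)) f$shared_id[which(f$has_shared_id)[1]]
                    else NA_character_,
        truth_id = paste(f$truth_id, collapse = ";"),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (cfg$nonfire_rows > 0 || cfg$pre2000_rows > 0) {
      junk <- list()
      for (j in seq_len(cfg$nonfire_rows)) {
        junk[[length(junk) + 1L]] <- data.frame(
          source = "ics209", source_id = sprintf("ICS-JUNK-%02d", j),
          name = "COVID-19 PANDEMIC RESPONSE", state = cfg$states[1],
          counties = NA_character_, ignition_date = "2020-03-15",
          containment_date = NA_character_, civilian_fatalities = NA_integer_,
          total_fatalities = 0L, destroyed_structures = 0L,
          damaged_structures = 0L, origin_lon = NA_real_, origin_lat = NA_real_,
          area_acres = NA_real_, shared_id = NA_character_,
          truth_id = NA_character_, stringsAsFactors = FALSE)
      }
      for (j in seq_len(cfg$pre2000_rows)) {
        junk[[length(junk) + 1L]] <- data.frame(
          source = "ics209", source_id = sprintf("ICS-OLD-%02d", j),
          name = paste("LEGACY", FIRE_WORDS[j]), state = cfg$states[1],
          counties = NA_character_, ignition_date = sprintf("19%02d-07-01", 90 + j),
          containment_date = NA_character_, civilian_fatalities = NA_integer_,
          total_fatalities = 0L, destroyed_structures = 1L,
          damaged_structures = 0L, origin_lon = NA_real_, origin_lat = NA_real_,
          area_acres = 100, shared_id = NA_character_,
          truth_id = NA_character_, stringsAsFactors = FALSE)
      }
      out <- rbind(out, do.call(rbind, junk))
    }
  } else if (flavor == "redbooks") {
    # individual fires, assigned-state only, large-fire threshold
    sel <- truth$state == cfg$redbooks_state |
      grepl(cfg$redbooks_state, truth$state, fixed = TRUE)
    f <- truth[sel & truth$area_acres >= cfg$redbooks_min_acres, , drop = FALSE]
    if (nrow(f) == 0L) return(empty_source_table("redbooks"))
    yr <- as.integer(format(f$ignition_date, "%Y"))
    combined_era <- yr >= 2007 & yr <= 2009
    cty <- vapply(f$counties, function(tg) {
      sc <- split_counties(tg)
      paste(sc$counties, collapse = ";")
    }, character(1))
    out <- data.frame(
      source = "redbooks",
      source_id = paste0("RB-", f$truth_id),
      name = f$name,
      state = cfg$redbooks_state,       # all events assumed in this state
      counties = cty,
      ignition_date = format(f$ignition_date, "%m/%d/%Y"),
      containment_date = format(f$containment_date, "%m/%d/%Y"),
      civilian_fatalities = f$civilian_fatalities,
      total_fatalities = f$civilian_fatalities + f$responder_fatalities,
      destroyed_structures = ifelse(combined_era, NA_integer_, f$destroyed_structures),
      damaged_structures = ifelse(combined_era, NA_integer_, f$damaged_structures),
      combined_damaged_destroyed = ifelse(
        combined_era, f$destroyed_structures + f$damaged_structures, NA_integer_),
      area_acres = f$area_acres,
      truth_id = f$truth_id,
      stringsAsFactors = FALSE)
  } else {
    units <- reporting_units(truth[truth$fmag, , drop = FALSE])
    if (length(units) == 0L) return(empty_source_table("fmag"))
    rows <- lapply(units, function(ix) {
      f <- truth[truth$fmag, , drop = FALSE][ix, , drop = FALSE]
      sc <- split_counties(unique(unlist(f$counties)))
      data.frame(
        source = "fmag",
        source_id = paste0("FM-", f$truth_id[1]),
        name = f$name[1],
        state = paste(sc$states, collapse = ";"),
        counties = paste(sc$counties, collapse = ";"),
        ignition_date = format(min(f$ignition_date), "%Y-%m-%d"),
        containment_date = format(max(f$containment_date), "%Y-%m-%d"),
        fmag_declaration_date = format(min(f$ignition_date) + 2, "%Y-%m-%d"),
        truth_id = paste(f$truth_id, collapse = ";"),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL

  # reproducible name/county perturbations (dates were jittered up front)
  real <- !is.na(out$truth_id)
  out$name[real] <- perturb_name(out$name[real], noise$name_edit_prob)
  if (noise$county_drop_prob > 0) {
    for (i in which(real)) {
      cs <- strsplit(out$counties[i], ";")[[1]]
      if (length(cs) > 1L && stats::runif(1) < noise$county_drop_prob) {
        out$counties[i] <- paste(cs[-sample.int(length(cs), 1)], collapse = ";")
      }
    }
  }
  out
}

empty_source_table <- function(source) {
  data.frame(source = character(0), source_id = character(0), name = character(0),
             state = character(0), counties = character(0),
             ignition_date = character(0), containment_date = character(0),
             truth_id = character(0), stringsAsFactors = FALSE)
}

#' Render the truth registry into a perimeter set
#'
#' @param truth the `fires` registry from [generate_truth()].
#' @param flavor one of `"mtbs"`, `"fired"`, `"nifc"`.
#' @param seed integer seed.
#' @param config the generating [world_config()].
#' @return data.frame with a `polygon` list-column; per-flavor identifying
#'   fields follow the corresponding real product (MTBS-like: regional size
#'   cutoffs, name + optional shared id + ignition date; FIRED-like: geometry
#'   and dates only; NIFC-like: name, shared id, ignition year only).
#' @export
render_perimeters <- function(truth, flavor = c("mtbs", "fired", "nifc"),
                              seed = 1, config = world_config()) {
  flavor <- match.arg(flavor)
  set.seed(sub_seed(seed, paste0("perims_", flavor)))
  cfg <- config
  if (flavor == "mtbs") {
    cut <- ifelse(truth$east, cfg$mtbs_min_acres_east, cfg$mtbs_min_acres_west)
    f <- truth[truth$in_mtbs & truth$area_acres >= cut, , drop = FALSE]
    out <- data.frame(flavor = rep("mtbs", nrow(f)),
                      perimeter_id = sprintf("MTBS-%s", f$truth_id),
                      name = f$name,
                      shared_id = f$shared_id,
                      ignition_date = f$ignition_date,
                      area_acres = f$area_acres,
                      truth_id = f$truth_id,
                      stringsAsFactors = FALSE)
    out$polygon <- f$perimeter
  } else if (flavor == "fired") {
    f <- truth[truth$in_fired, , drop = FALSE]
    out <- data.frame(flavor = rep("fired", nrow(f)),
                      perimeter_id = sprintf("FIRED-%s", f$truth_id),
                      ignition_date = f$ignition_date,
                      containment_date = f$containment_date,
                      area_acres = f$area_acres,
                      truth_id = f$truth_id,
                      stringsAsFactors = FALSE)
    out$polygon <- f$perimeter
  } else {
    f <- truth[truth$in_nifc, , drop = FALSE]
    out <- data.frame(flavor = rep("nifc", nrow(f)),
                      perimeter_id = sprintf("NIFC-%s", f$truth_id),
                      name = f$name,
                      shared_id = f$shared_id,
                      year = as.integer(format(f$ignition_date, "%Y")),
                      area_acres = f$area_acres,
                      truth_id = f$truth_id,
                      stringsAsFactors = FALSE)
    out$polygon <- f$perimeter
  }
  rownames(out) <- NULL
  out
}

#' Evaluate one town-kernel population grid for an epoch
#'
#' Cell values are the sum of isotropic Gaussian town kernels at cell
#' centres, scaled by a mild compounding growth factor per 5-year epoch, and
#' floored to integers.
#'
#' @param world a `synthetic_world`.
#' @param epoch_year a multiple of 5 (e.g. 2010).
#' @return a [burn_grid()] of people per cell.
#' @export
generate_population_grid <- function(world, epoch_year = 2020) {
  if (epoch_year %% 5 != 0) stop("epoch_year must be a multiple of 5")
  growth <- 1.08 ^ ((epoch_year - 2000) / 5)
  ncell <- nrow(world$housing$values)
  vals <- matrix(0, ncell, ncell)
  ctr <- (seq_len(ncell) - 0.5) * world$cell_km
  for (t in seq_len(nrow(world$towns))) {
    tw <- world$towns[t, ]
    ix <- which(abs(ctr - tw$x) <= 4 * tw$sd_km)
    iy <- which(abs(ctr - tw$y) <= 4 * tw$sd_km)
    if (!length(ix) || !length(iy)) next
    gx <- exp(-((ctr[ix] - tw$x)^2) / (2 * tw$sd_km^2))
    gy <- exp(-((ctr[iy] - tw$y)^2) / (2 * tw$sd_km^2))
    vals[iy, ix] <- vals[iy, ix] + tw$peak * growth * outer(gy, gx)
  }
  burn_grid(floor(vals), cell = world$cell_km, frame = world$frame)
}
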
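# Name, county and date standardization across source tables.
#
# Fire names are uppercased, stripped of punctuation, and whole tokens are
# replaced by their USPS standard abbreviation ("MOUNTAIN" -> "MTN"); county
# names are matched against a gazetteer with an alias rule for frequently
# abbreviated counties; rows ignited before 2000 and non-fire rows (COVID-19
# style declarations) are dropped with a reasoned rejection log.

UNRESOLVED_COUNTY <- "__UNRESOLVED__"

#' Bundled USPS-style abbreviation table
#' @return data.frame with columns `word`, `abbreviation` (uppercase).
#' @export
usps_abbreviations <- function() {
  path <- system.file("extdata", "usps_abbreviations.csv", package = "burnzones")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Standardize a fire/incident name
#'
#' Uppercases, strips punctuation, collapses whitespace, and replaces each
#' whole token found in the abbreviation table ("MOUNTAIN" becomes "MTN";
#' "MOUNTAINEER" is left alone).  Idempotent.
#'
#' @param raw character vector of raw names.
#' @param abbreviations data.frame(word, abbreviation); default the bundled
#'   USPS table.
#' @return character vector of standardized names.
#' @examples
#' standardize_name("Mountain Fire")  # "MTN FIRE"
#' @export
standardize_name <- function(raw, abbreviations = usps_abbreviations()) {
  x <- toupper(as.character(raw))
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  map <- stats::setNames(toupper(abbreviations$abbreviation),
                         toupper(abbreviations$word))
  vapply(x, function(s) {
    if (is.na(s) || s == "") return(s)
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    hit <- toks %in% names(map)
    toks[hit] <- map[toks[hit]]
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a county gazetteer
#'
#' @param counties data.frame with columns `state`, `county` (canonical names)
#'   and optionally a list-column `polygon` of planar vertex matrices.
#' @param aliases data.frame(state, alias, canonical), e.g. the "LA" family of
#'   Los Angeles abbreviations; may be empty.
#' @return object of class `gazetteer`.
#' @export
gazetteer <- function(counties, aliases = NULL) {
  stopifnot(all(c("state", "county") %in% names(counties)))
  counties$state <- toupper(counties$state)
  counties$county <- toupper(counties$county)
  if (anyDuplicated(counties[c("state", "county")]))
    stop("canonical county names must be unique within state")
  if (is.null(aliases))
    aliases <- data.frame(state = character(), alias = character(),
                          canonical = character())
  aliases$state <- toupper(aliases$state)
  aliases$alias <- toupper(aliases$alias)
  aliases$canonical <- toupper(aliases$canonical)
  structure(list(counties = counties, aliases = aliases), class = "gazetteer")
}

#' Resolve a raw county name against the gazetteer
#'
#' Exact (case-insensitive, "COUNTY" suffix ignored) and alias matches return
#' the canonical name; anything else returns the unresolved sentinel and the
#' caller keeps the record.
#'
#' @param raw character vector of raw county names.
#' @param state two-letter state (scalar or vector).
#' @param gaz a [gazetteer()].
#' @param la_alias enable the "LA"-style alias rule (default TRUE).
#' @return character vector of canonical names or `UNRESOLVED_COUNTY`.
#' @export
standardize_county <- function(raw, state, gaz, la_alias = TRUE) {
  n <- max(length(raw), length(state))
  raw <- rep_len(as.character(raw), n)
  state <- rep_len(toupper(as.character(state)), n)
  known <- unique(gaz$counties$state)
  bad <- setdiff(unique(state[!is.na(state)]), known)
  if (length(bad)) stop("unknown gazetteer state(s): ", paste(bad, collapse = ", "))
  out <- character(n)
  for (k in seq_len(n)) {
    if (is.na(raw[k])) { out[k] <- UNRESOLVED_COUNTY; next }
    s <- toupper(gsub("\\s+", " ", trimws(raw[k])))
    s <- sub(" (COUNTY|CO\\.?)$", "", s)
    cands <- gaz$counties$county[gaz$counties$state == state[k]]
    if (s %in% cands) { out[k] <- s; next }
    al <- gaz$aliases[gaz$aliases$state == state[k] & gaz$aliases$alias == s, ]
    if (nrow(al)) { out[k] <- al$canonical[1]; next }
    if (la_alias && grepl("^LA( |$)", s) && "LOS ANGELES" %in% cands) {
      out[k] <- "LOS ANGELES"; next
    }
    out[k] <- UNRESOLVED_COUNTY
  }
  out
}

# Try the accepted date dialects in order; returns Date or NA.
parse_event_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA, length(x)))
  for (fmt in c("%Y-%m-%d", "%m/%d/%Y")) {
    miss <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(miss)) break
    out[miss] <- as.Date(x[miss], format = fmt)
  }
  out
}

#' Clean a rendered source table into standardized event records
#'
#' Applies name standardization, county resolution, date parsing, the
#' pre-2000 ignition-year filter and non-fire pattern removal.  Cleaning is
#' idempotent and conservative: `nrow(input) == nrow(output) + nrow(rejections)`.
#'
#' @param table a source-flavored data.frame (see [render_sources()]); must
#'   carry `source`, `source_id`, `name`, `state`, `counties` (";"-separated),
#'   and the per-source date/count fields.
#' @param gaz a [gazetteer()].
#' @param min_year drop rows ignited before this year (default 2000).
#' @param nonfire_patterns regexes on the standardized name marking rows that
#'   are not wildfires (default `"COVID"`).
#' @param abbreviations abbreviation table for [standardize_name()].
#' @return list with `records` (standardized data.frame, list-columns
#'   `states`/`counties`) and `rejections` (source, source_id, reason).
#' @export
clean_events <- function(table, gaz, min_year = 2000,
                         nonfire_patterns = c("COVID"),
                         abbreviations = usps_abbreviations()) {
  # accept our own output so that cleaning is idempotent
  if (!"name" %in% names(table) && "clean_name" %in% names(table))
    table$name <- table$clean_name
  collapse_listcol <- function(col) {
    vapply(col, function(v) {
      v <- unique(v[!is.na(v)])
      if (length(v) == 0L) NA_character_ else paste(v, collapse = ";")
    }, character(1))
  }
  prepaired <- is.list(table[["states"]]) && is.list(table[["counties"]])
  if (prepaired) {
    pair_states <- table$states
    pair_counties <- table$counties
  }
  if (is.list(table[["states"]])) table$state <- collapse_listcol(table$states)
  if (is.list(table[["counties"]])) table$counties <- collapse_listcol(table$counties)
  stopifnot(all(c("source", "source_id", "name") %in% names(table)))
  n <- nrow(table)
  clean_name <- standardize_name(table$name, abbreviations)

  ign <- parse_event_date(table[["ignition_date"]] %||% rep(NA, n))
  con <- parse_event_date(table[["containment_date"]] %||% rep(NA, n))
  dec <- parse_event_date(table[["fmag_declaration_date"]] %||%
                            table[["declaration_date"]] %||% rep(NA, n))
  year <- table[["year"]] %||% rep(NA_integer_, n)
  year <- ifelse(!is.na(ign), as.integer(format(ign, "%Y")), as.integer(year))
  # FMAG rows without an ignition date fall back to the declaration year
  year <- ifelse(is.na(year) & !is.na(dec), as.integer(format(dec, "%Y")), year)

  reason <- rep(NA_character_, n)
  nf <- rep(FALSE, n)
  for (p in nonfire_patterns) nf <- nf | grepl(p, clean_name, ignore.case = TRUE)
  reason[nf] <- "non_fire"
  pre <- !nf & !is.na(year) & year < min_year
  reason[pre] <- "pre_2000"
  noyear <- is.na(reason) & is.na(year)
  reason[noyear] <- "unparseable_date"

  keep <- is.na(reason)
  states_raw <- as.character(table[["state"]] %||% rep(NA, n))
  counties_raw <- as.character(table[["counties"]] %||% table[["county"]] %||% rep(NA, n))

  states <- vector("list", n)
  counties <- vector("list", n)
  for (k in which(keep)) {
    if (prepaired) {
      # already-cleaned input: state-county pairs are parallel; resolving them
      # pairwise (not as a cross product) keeps cleaning idempotent
      st_p <- toupper(pair_states[[k]])
      ct_p <- pair_counties[[k]]
      if (length(ct_p) && length(st_p)) {
        m <- max(length(st_p), length(ct_p))
        st_p <- rep_len(st_p, m); ct_p <- rep_len(ct_p, m)
        ok <- !is.na(st_p)
        canon <- standardize_county(ct_p[ok], st_p[ok], gaz)
        dup <- duplicated(paste(st_p[ok], canon))
        states[[k]] <- st_p[ok][!dup]
        counties[[k]] <- canon[!dup]
      } else {
        states[[k]] <- if (length(st_p)) st_p else NA_character_
        counties[[k]] <- character(0)
      }
      next
    }
    sr <- if (is.na(states_raw[k])) "" else states_raw[k]
    st <- unique(toupper(trimws(strsplit(sr, ";")[[1]])))
    st <- st[nzchar(st)]
    cr <- trimws(strsplit(if (is.na(counties_raw[k])) "" else counties_raw[k], ";")[[1]])
    cr <- unique(cr[nzchar(cr)])
    if (length(st) == 0L) st <- NA_character_
    # all combinations of state and county name are retained
    if (length(cr)) {
      combo <- expand.grid(state = st, county = cr, stringsAsFactors = FALSE)
      combo$canonical <- standardize_county(combo$county, combo$state, gaz)
      dup <- duplicated(paste(combo$state, combo$canonical))
      states[[k]] <- combo$state[!dup]
      counties[[k]] <- combo$canonical[!dup]
    } else {
      states[[k]] <- st
      counties[[k]] <- character(0)
    }
  }

  num_or_na <- function(col) {
    v <- table[[col]] %||% rep(NA_real_, n)
    suppressWarnings(as.numeric(v))
  }
  rec <- data.frame(
    source = as.character(table$source),
    source_id = as.character(table$source_id),
    raw_name = as.character(table$name),
    clean_name = clean_name,
    year = year,
    stringsAsFactors = FALSE)
  rec$ignition_date <- ign
  rec$containment_date <- con
  rec$fmag_declaration_date <- dec
  rec$states <- states
  rec$counties <- counties
  for (col in c("civilian_fatalities", "total_fatalities", "destroyed_structures",
                "damaged_structures", "combined_damaged_destroyed",
                "origin_lon", "origin_lat", "area_acres")) {
    rec[[col]] <- num_or_na(col)
  }
  rec$shared_id <- as.character(table[["shared_id"]] %||% rep(NA_character_, n))
  rec$truth_id <- as.character(table[["truth_id"]] %||% rep(NA_character_, n))

  list(records = rec[keep, , drop = FALSE],
       rejections = data.frame(source = as.character(table$source[!keep]),
                               source_id = as.character(table$source_id[!keep]),
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
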
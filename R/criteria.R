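# Harm criteria with era-dependent fallbacks.
#
# fatality : >= 1 civilian fatality, or (ignition year 2000-2013, when the
#            incident-report schema did not break out civilian deaths) >= 1
#            fatality of any type.
# structure: >= 1 destroyed structure, or (2007-2009, when the state annual
#            reports combined damaged and destroyed) >= 1 damaged/destroyed.
# fmag     : the fire appears in the federal fire-assistance source.
# Eras key on ignition year; fires with no usable year are evaluated under
# the strict rules and annotated.

#' Evaluate the three harm criteria for canonical fires
#'
#' @param fires canonical-fire data.frame from [resolve_all()].
#' @return `fires` with logical columns `fatality_met`, `structure_met`,
#'   `fmag_met` and annotation columns `fatality_rule`, `structure_rule`,
#'   `fmag_rule` recording which rule fired.
#' @export
evaluate_criteria <- function(fires) {
  n <- nrow(fires)
  yr <- fires$year
  civ <- fires$civilian_fatalities
  tot <- fires$total_fatalities
  destr <- fires$destroyed_structures
  comb <- fires$combined_damaged_destroyed

  fat <- !is.na(civ) & civ >= 1
  fat_rule <- ifelse(fat, "civilian", "none")
  fb <- !fat & !is.na(yr) & yr >= 2000 & yr <= 2013 & !is.na(tot) & tot >= 1
  fat[fb] <- TRUE
  fat_rule[fb] <- "any_fatality_fallback_2000_2013"

  st <- !is.na(destr) & destr >= 1
  st_rule <- ifelse(st, "destroyed", "none")
  sfb <- !st & !is.na(yr) & yr >= 2007 & yr <= 2009 & !is.na(comb) & comb >= 1
  st[sfb] <- TRUE
  st_rule[sfb] <- "damaged_fallback_2007_2009"

  fm <- isTRUE_vec(fires$fmag)
  fm_rule <- ifelse(fm, "fmag", "none")

  noyr <- is.na(yr)
  fat_rule[noyr & fat_rule == "none"] <- "none_strict_no_year"
  st_rule[noyr & st_rule == "none"] <- "none_strict_no_year"

  fires$fatality_met <- fat
  fires$structure_met <- st
  fires$fmag_met <- fm
  fires$fatality_rule <- fat_rule
  fires$structure_rule <- st_rule
  fires$fmag_rule <- fm_rule
  fires
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Filter to the preliminary disaster set
#'
#' Retains exactly the fires meeting at least one harm criterion.
#'
#' @param fires output of [evaluate_criteria()].
#' @return list with `preliminary` (retained rows) and `counts` (named vector
#'   of per-criterion and total counts).
#' @export
filter_preliminary <- function(fires) {
  stopifnot(all(c("fatality_met", "structure_met", "fmag_met") %in% names(fires)))
  keep <- fires$fatality_met | fires$structure_met | fires$fmag_met
  list(preliminary = fires[keep, , drop = FALSE],
       counts = c(fatality = sum(fires$fatality_met),
                  structure = sum(fires$structure_met),
                  fmag = sum(fires$fmag_met),
                  any = sum(keep),
                  total = nrow(fires)))
}
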
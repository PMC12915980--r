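#' The twelve vessel type labels
#'
#' The taxonomy covers the categories found in AIS (Automatic Identification
#' System) static data after splitting cruise ships and ferries out of the
#' generic "Passenger" class, plus an "other" bucket for specialty vessels
#' (crew boats, cable layers, dredgers, ...). Every label maps to exactly one
#' deadweight-to-displacement strategy ([dwt_strategies()]) and one row of
#' the published coefficient bundle ([load_published_bundle()]).
#'
#' @return Character vector of the twelve canonical labels.
#' @examples
#' vessel_types()
#' @export
vessel_types <- function() {
  c(
    "bulk_carrier", "container_ship", "cruise", "ferry", "fishing",
    "government_research", "other", "passenger", "pleasure_craft",
    "sailing", "tanker", "tug"
  )
}

#' Normalise vessel type labels to the canonical taxonomy
#'
#' Lower-cases, maps spaces, hyphens and slashes to underscores, and accepts
#' a few common aliases (e.g. "Government/Research", "cruise ship"). Unknown
#' labels raise an error naming the offending values.
#'
#' @param x Character vector of type labels.
#' @return Character vector of canonical labels (same length as `x`).
#' @examples
#' as_vessel_type(c("Cruise ship", "Government/Research", "TUG"))
#' @export
as_vessel_type <- function(x) {
  canon <- tolower(trimws(as.character(x)))
  canon <- gsub("[ /-]+", "_", canon)
  aliases <- c(
    cruise_ship = "cruise",
    government = "government_research",
    research = "government_research",
    sailboat = "sailing",
    sailing_vessel = "sailing",
    fishing_vessel = "fishing",
    yacht = "pleasure_craft"
  )
  hit <- canon %in% names(aliases)
  canon[hit] <- aliases[canon[hit]]
  bad <- !is.na(canon) & !(canon %in% vessel_types())
  if (any(bad)) {
    abort(sprintf(
      "Unknown vessel type(s): %s. Expected one of: %s.",
      paste(unique(canon[bad]), collapse = ", "),
      paste(vessel_types(), collapse = ", ")
    ))
  }
  canon
}
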
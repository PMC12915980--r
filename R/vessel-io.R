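#' Default column-name dialect for vessel tables
#'
#' Maps the canonical field names used internally to the column names
#' expected in a CSV file. Override any entry (e.g. `loa_m = "length"`) to
#' read files with different headers, or supply the mapping as a YAML/JSON
#' file to [read_vessel_table()].
#'
#' @return Named character vector: canonical field -> column name.
#' @export
default_dialect <- function() {
  c(
    record_id = "record_id",
    vessel_type = "vessel_type",
    loa_m = "loa_m",
    dwt_tonnes = "dwt_tonnes",
    displacement_kg = "displacement_kg",
    net_weight_kg = "net_weight_kg",
    capacity_persons = "capacity_persons",
    source = "source",
    gross_tonnage = "gross_tonnage"
  )
}

read_dialect_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Package 'yaml' is required to read YAML dialect files.")
    }
    unlist(yaml::read_yaml(path))
  } else {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

# LOA outside this span is flagged as implausible (warning, not error); the
# span generously brackets observed fleets (smallest dinghies to the longest
# container ships ever built).
loa_plausible_range <- c(3, 450)

#' Read a table of vessel records
#'
#' Reads an AIS-static-like CSV of vessel characteristics into a validated
#' tibble of vessel records. Each retained row satisfies the record
#' invariants: a known vessel type, `loa_m > 0`, at least one of
#' `dwt_tonnes`, `displacement_kg`, `net_weight_kg` present, `dwt_tonnes >= 0`
#' and `displacement_kg > 0` where present. Rows violating an invariant (or
#' with unparseable numerics) are dropped from the result but reported in a
#' warning naming their `record_id`, and returned in the `"problems"`
#' attribute. Gross tonnage, a volume measure unsuitable for mass
#' estimation, is carried through untouched when present.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Optional column-name mapping: a named vector/list
#'   overriding entries of [default_dialect()], or the path to a YAML/JSON
#'   file holding such a mapping.
#' @return A tibble with columns `record_id`, `vessel_type`, `loa_m`,
#'   `dwt_tonnes`, `displacement_kg`, `net_weight_kg`, `capacity_persons`,
#'   `source` (plus `gross_tonnage` when present in the file), one row per
#'   valid record; invalid rows are described in `attr(, "problems")`.
#' @seealso [validate_vessel_records()], [dedupe_fleet()],
#'   [write_vessel_table()]
#' @export
read_vessel_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect) &&
      is.null(names(dialect))) {
    dialect <- read_dialect_file(dialect)
  }
  map <- default_dialect()
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    unknown <- setdiff(names(dialect), names(map))
    if (length(unknown)) {
      abort(sprintf(
        "Unknown dialect field(s): %s.", paste(unknown, collapse = ", ")
      ))
    }
    map[names(dialect)] <- dialect
  }

  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  for (field in c("vessel_type", "loa_m")) {
    if (!(map[[field]] %in% names(raw))) {
      abort(sprintf(
        "Required column '%s' (field %s) not found in %s.",
        map[[field]], field, path
      ))
    }
  }

  pick <- function(field) {
    col <- map[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  records <- tibble::tibble(
    record_id = pick("record_id"),
    vessel_type = pick("vessel_type"),
    loa_m = num(pick("loa_m")),
    dwt_tonnes = num(pick("dwt_tonnes")),
    displacement_kg = num(pick("displacement_kg")),
    net_weight_kg = num(pick("net_weight_kg")),
    capacity_persons = num(pick("capacity_persons")),
    source = pick("source")
  )
  if (map[["gross_tonnage"]] %in% names(raw)) {
    records$gross_tonnage <- num(pick("gross_tonnage"))
  }
  records$record_id <- ifelse(
    is.na(records$record_id) | records$record_id == "",
    sprintf("row_%d", seq_len(nrow(records))),
    records$record_id
  )
  records$source <- ifelse(
    is.na(records$source) | records$source == "",
    ifelse(is.na(records$dwt_tonnes), "online", "ais"),
    records$source
  )

  # flag numerics that were present as text but failed to parse
  parse_problem <- function(field) {
    txt <- pick(field)
    present <- !is.na(txt) & txt != ""
    present & is.na(num(txt))
  }
  unparseable <- parse_problem("loa_m") | parse_problem("dwt_tonnes") |
    parse_problem("displacement_kg") | parse_problem("net_weight_kg") |
    parse_problem("capacity_persons")

  checked <- validate_vessel_records(records, unparseable = unparseable)
  out <- checked$records
  problems <- checked$problems
  if (nrow(problems) > 0) {
    warn(sprintf(
      "%d row(s) failed validation and were dropped: %s",
      nrow(problems),
      paste(sprintf("%s (%s)", problems$record_id, problems$problem),
            collapse = "; ")
    ))
  }
  attr(out, "problems") <- problems
  out
}

#' Validate vessel records against the record invariants
#'
#' @param records A tibble shaped like the output of [read_vessel_table()].
#' @param unparseable Optional logical vector marking rows whose numeric
#'   fields could not be parsed.
#' @return A list with `records` (the valid rows, types canonicalised) and
#'   `problems` (tibble of `record_id`, `problem` for the rejected rows).
#' @export
validate_vessel_records <- function(records, unparseable = NULL) {
  n <- nrow(records)
  if (is.null(unparseable)) unparseable <- rep(FALSE, n)
  problem <- rep(NA_character_, n)

  type_ok <- rep(TRUE, n)
  canon <- records$vessel_type
  for (i in seq_len(n)) {
    ti <- tryCatch(as_vessel_type(records$vessel_type[i]), error = function(e) NA)
    if (is.na(ti)) type_ok[i] <- FALSE else canon[i] <- ti
  }
  records$vessel_type <- canon

  has_mass <- !is.na(records$dwt_tonnes) | !is.na(records$displacement_kg) |
    !is.na(records$net_weight_kg)

  problem[unparseable] <- "unparseable numeric field"
  problem[is.na(problem) & !type_ok] <- "unknown vessel type"
  problem[is.na(problem) & (is.na(records$loa_m) | records$loa_m <= 0)] <-
    "loa_m must be > 0"
  problem[is.na(problem) & !has_mass] <-
    "needs one of dwt_tonnes, displacement_kg, net_weight_kg"
  problem[is.na(problem) & !is.na(records$dwt_tonnes) & records$dwt_tonnes < 0] <-
    "dwt_tonnes must be >= 0"
  problem[is.na(problem) & !is.na(records$displacement_kg) &
            records$displacement_kg <= 0] <- "displacement_kg must be > 0"
  problem[is.na(problem) & !is.na(records$capacity_persons) &
            (records$capacity_persons < 0 |
               records$capacity_persons != round(records$capacity_persons))] <-
    "capacity_persons must be a non-negative integer"

  bad <- !is.na(problem)
  valid <- records[!bad, , drop = FALSE]
  odd_loa <- valid$loa_m < loa_plausible_range[1] |
    valid$loa_m > loa_plausible_range[2]
  if (any(odd_loa)) {
    warn(sprintf(
      "Implausible LOA outside [%g m, %g m] for record(s): %s",
      loa_plausible_range[1], loa_plausible_range[2],
      paste(valid$record_id[odd_loa], collapse = ", ")
    ))
  }
  list(
    records = valid,
    problems = tibble::tibble(
      record_id = records$record_id[bad],
      problem = problem[bad]
    )
  )
}

#' Drop replicate vessels of the same model
#'
#' Two listings of the same vessel model — same type, same LOA and same
#' maximum deadweight tonnage — carry no extra information for a
#' length-mass regression, so only one replicate is kept. Records without a
#' DWT value are deduplicated on (type, LOA, displacement) instead. The
#' first occurrence in input order wins; the operation is idempotent.
#'
#' @param records A validated tibble of vessel records.
#' @return The records with replicates removed, original order preserved.
#' @export
dedupe_fleet <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- ifelse(
    !is.na(records$dwt_tonnes),
    paste(records$vessel_type, records$loa_m, "dwt", records$dwt_tonnes),
    paste(records$vessel_type, records$loa_m, "disp", records$displacement_kg)
  )
  records[!duplicated(key), , drop = FALSE]
}

#' Write vessel records to CSV
#'
#' Writes the standard vessel schema (plus any estimate columns such as
#' `displacement_est_kg` and `method`) with enough digits that values with
#' up to 15 significant digits round-trip through [read_vessel_table()].
#'
#' @param records Tibble of vessel records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vessel_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
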
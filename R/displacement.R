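#' Estimate displacement for a table of vessel records
#'
#' Dispatches each record through the displacement-estimation cascade:
#'
#' 1. a reported `displacement_kg` is returned unchanged (method
#'    `"reported"`);
#' 2. otherwise a reported `net_weight_kg` is corrected for maximum persons
#'    capacity via [net_weight_to_displacement()] (method `"net_weight"`);
#' 3. otherwise the vessel type's deadweight strategy converts `dwt_tonnes`:
#'    bulk carriers, container ships, tankers and tugs use their published
#'    conversion equations (method `"dwt_equation"`); cruise, ferry,
#'    fishing, passenger, pleasure craft and sailing use the fixed per-type
#'    deadweight coefficient, displacement = DWT / C_D (method
#'    `"dwt_ratio"`); government/research and "other" average the
#'    container-ship, stern-trawler and small-passenger estimates after
#'    each is converted to kg (method `"dwt_mixed"`).
#'
#' @param records A validated tibble of vessel records (see
#'   [read_vessel_table()]).
#' @param strategies Strategy table from [dwt_strategies()].
#' @param cd_mode `"fixed"` (default) uses one deadweight coefficient per
#'   type, anchored at the reference sample's average LOA; `"interpolated"`
#'   re-interpolates the coefficient at each record's own LOA (opt-in).
#' @return `records` with `displacement_est_kg` and `method` columns
#'   appended.
#' @examples
#' fleet <- tibble::tibble(
#'   record_id = "t1", vessel_type = "tug", loa_m = 44.1,
#'   dwt_tonnes = 952, displacement_kg = NA_real_,
#'   net_weight_kg = NA_real_, capacity_persons = NA_real_, source = "ais"
#' )
#' estimate_displacement(fleet)
#' @export
estimate_displacement <- function(records, strategies = dwt_strategies(),
                                  cd_mode = c("fixed", "interpolated")) {
  cd_mode <- match.arg(cd_mode)
  needed <- c("record_id", "vessel_type", "loa_m")
  if (!all(needed %in% names(records))) {
    abort(sprintf(
      "records must carry columns: %s.", paste(needed, collapse = ", ")
    ))
  }
  for (col in c("dwt_tonnes", "displacement_kg", "net_weight_kg",
                "capacity_persons")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }

  n <- nrow(records)
  est <- rep(NA_real_, n)
  method <- rep(NA_character_, n)

  reported <- !is.na(records$displacement_kg)
  est[reported] <- records$displacement_kg[reported]
  method[reported] <- "reported"

  net <- !reported & !is.na(records$net_weight_kg)
  if (any(net)) {
    est[net] <- net_weight_to_displacement(
      records$net_weight_kg[net], records$capacity_persons[net]
    )
    method[net] <- "net_weight"
  }

  dwt_route <- !reported & !net & !is.na(records$dwt_tonnes)
  if (any(dwt_route)) {
    idx <- which(dwt_route)
    for (type in unique(records$vessel_type[idx])) {
      rows <- idx[records$vessel_type[idx] == type]
      est[rows] <- strategy_mass_kg(
        type, records$dwt_tonnes[rows], strategies,
        cd_mode = cd_mode, loa_m = records$loa_m[rows]
      )
      kind <- strategies[[type]]$kind
      method[rows] <- switch(kind,
        rule = "dwt_equation", ratio = "dwt_ratio", mixed = "dwt_mixed"
      )
    }
  }

  unusable <- is.na(method)
  if (any(unusable)) {
    abort(sprintf(
      "No usable mass field (displacement, net weight or DWT) for record(s): %s.",
      paste(records$record_id[unusable], collapse = ", ")
    ))
  }
  records$displacement_est_kg <- est
  records$method <- method
  records
}
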
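#' Build a deadweight-to-displacement conversion rule
#'
#' A conversion rule turns a maximum deadweight tonnage (DWT, tonnes) into
#' a displacement. Three functional forms occur in the source tables:
#' `ratio` (displacement = scale * DWT), `linear`
#' (scale * DWT + offset) and `power` (scale * DWT^exponent). Some source
#' equations yield U.S. customary tons (1016 kg) rather than metric tonnes;
#' the rule's `output_unit` records that dialect and [apply_dwt_rule()]
#' converts the result to kg accordingly.
#'
#' @param form One of `"ratio"`, `"linear"`, `"power"`.
#' @param scale Positive multiplier.
#' @param exponent Exponent (power form only).
#' @param offset Additive offset (linear form only).
#' @param output_unit `"tonnes"` or `"us_tons"`.
#' @param source_label Free-text citation for the rule.
#' @return An object of class `dwt_rule`.
#' @examples
#' tug <- dwt_rule("power", 5.2301, exponent = 0.8752, output_unit = "tonnes")
#' apply_dwt_rule(tug, 952)
#' @export
dwt_rule <- function(form = c("ratio", "linear", "power"), scale,
                     exponent = NULL, offset = NULL,
                     output_unit = c("tonnes", "us_tons"),
                     source_label = "") {
  form <- match.arg(form)
  output_unit <- match.arg(output_unit)
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  if (form == "power" && is.null(exponent)) {
    abort("A power rule needs an exponent.")
  }
  if (form == "linear" && is.null(offset)) {
    abort("A linear rule needs an offset.")
  }
  structure(
    list(
      form = form, scale = scale,
      exponent = if (form == "power") exponent else NULL,
      offset = if (form == "linear") offset else NULL,
      output_unit = output_unit, source_label = source_label
    ),
    class = "dwt_rule"
  )
}

#' Evaluate a conversion rule, returning kilograms
#'
#' Applies the rule's functional form to a DWT value and converts the
#' result to kg (x1000 for tonnes, x1016 for U.S. tons).
#'
#' @param rule A [dwt_rule()].
#' @param dwt Numeric vector of deadweight tonnages, `>= 0`.
#' @return Displacement(s) in kg.
#' @export
apply_dwt_rule <- function(rule, dwt) {
  stopifnot(inherits(rule, "dwt_rule"), is.numeric(dwt))
  if (any(is.na(dwt)) || any(dwt < 0)) abort("dwt must be non-negative.")
  raw <- switch(rule$form,
    ratio = rule$scale * dwt,
    linear = rule$scale * dwt + rule$offset,
    power = rule$scale * dwt^rule$exponent
  )
  unit_kg <- switch(rule$output_unit,
    tonnes = vm_units()$tonne_kg,
    us_tons = vm_units()$us_ton_kg
  )
  raw * unit_kg
}

#' Load the per-type conversion strategy table
#'
#' Reads the packaged strategy table (or a user override with the same
#' schema) mapping each of the twelve vessel types to its
#' deadweight-to-displacement strategy: an explicit equation (`rule`), a
#' fixed deadweight-coefficient ratio (`ratio`), or the mixed-category
#' scheme (`mixed`) that averages a container-ship equation estimate with
#' stern-trawler and small-passenger ratio estimates — all three converted
#' to kg before averaging.
#'
#' @param path Optional path to an alternative strategy JSON file.
#' @return A named list of strategies with attributes `version` and
#'   `provenance`.
#' @export
dwt_strategies <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dwt_strategies.json",
                                package = "vesselmass", mustWork = TRUE)
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  strategies <- spec$strategies
  missing <- setdiff(vessel_types(), names(strategies))
  if (length(missing)) {
    abort(sprintf(
      "Strategy table %s lacks vessel type(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  for (type in names(strategies)) {
    s <- strategies[[type]]
    ok <- switch(s$kind %||% "",
      rule = is.numeric(s$scale) && s$scale > 0,
      ratio = is.numeric(s$cd) && s$cd > 0 && s$cd < 1,
      mixed = is.numeric(s$cd_fishing) && is.numeric(s$cd_small_passenger),
      FALSE
    )
    if (!isTRUE(ok)) {
      abort(sprintf("Invalid strategy entry for type '%s' in %s.", type, path))
    }
  }
  structure(strategies,
            version = spec$version, provenance = spec$provenance)
}

as_rule <- function(s) {
  dwt_rule(s$form, s$scale,
           exponent = s$exponent, offset = s$offset,
           output_unit = s$output_unit,
           source_label = s$source_label %||% "")
}

# Ratio strategies invert the deadweight coefficient exactly:
# displacement_kg = dwt * 1000 / cd, so displacement * cd == dwt * 1000.
ratio_mass_kg <- function(dwt, cd) dwt * vm_units()$tonne_kg / cd

# Evaluate one type's strategy for a vector of DWT values. `loa_m` is only
# consulted in the opt-in per-record interpolation mode.
strategy_mass_kg <- function(type, dwt, strategies,
                             cd_mode = c("fixed", "interpolated"),
                             loa_m = NULL) {
  cd_mode <- match.arg(cd_mode)
  s <- strategies[[type]]
  if (is.null(s)) abort(sprintf("No strategy for vessel type '%s'.", type))
  pick_cd <- function(fixed, class) {
    if (cd_mode == "fixed" || is.null(loa_m)) fixed
    else interpolate_cd(cd_specs()[class, ], loa_m)
  }
  switch(s$kind,
    rule = apply_dwt_rule(as_rule(s), dwt),
    ratio = ratio_mass_kg(dwt, pick_cd(s$cd, s$cd_class)),
    mixed = {
      container <- apply_dwt_rule(as_rule(strategies$container_ship), dwt)
      fish <- ratio_mass_kg(dwt, pick_cd(s$cd_fishing, "stern_trawler"))
      pass <- ratio_mass_kg(dwt, pick_cd(s$cd_small_passenger, "small_passenger"))
      (container + fish + pass) / 3
    }
  )
}

# Invert a strategy: recover the DWT (tonnes) that maps to a displacement
# in kg. Ratio/power/linear forms invert analytically; the mixed average
# is solved numerically on the log-DWT scale.
invert_strategy_dwt <- function(type, displacement_kg, strategies) {
  s <- strategies[[type]]
  if (is.null(s)) abort(sprintf("No strategy for vessel type '%s'.", type))
  units <- vm_units()
  if (s$kind == "ratio") {
    return(displacement_kg * s$cd / units$tonne_kg)
  }
  if (s$kind == "rule") {
    unit_kg <- if (s$output_unit == "us_tons") units$us_ton_kg else units$tonne_kg
    raw <- displacement_kg / unit_kg
    return(switch(s$form,
      ratio = raw / s$scale,
      power = (raw / s$scale)^(1 / s$exponent),
      linear = {
        dwt <- (raw - s$offset) / s$scale
        if (any(dwt < 0)) {
          abort(sprintf(
            "Displacement below the linear rule's intercept for type '%s'.",
            type
          ))
        }
        dwt
      }
    ))
  }
  # mixed: strictly increasing in DWT, root-find on log scale
  vapply(displacement_kg, function(target) {
    guess <- max(target * 0.4 / units$tonne_kg, 1e-6)
    f <- function(u) strategy_mass_kg(type, exp(u), strategies) - target
    root <- uniroot(f, interval = log(guess) + c(-25, 25), tol = 1e-13)
    exp(root$root)
  }, numeric(1))
}

#' Convert a net (light-ship) weight to a maximum displacement
#'
#' Catalogue listings for small vessels often report only the net weight,
#' i.e. the light-ship weight of the empty vessel. The maximum displacement
#' is approximated by adding one average person (75 kg) plus one piece of
#' luggage (20 kg) per berth, times the maximum persons capacity. When the
#' capacity is unknown, a single person and their luggage are added — there
#' is at least one person aboard a moving vessel.
#'
#' @param net_weight_kg Numeric vector of light-ship weights in kg, `>= 0`.
#' @param capacity_persons Optional vector of maximum persons onboard
#'   (non-negative; `NA` triggers the one-person fallback).
#' @return Displacement(s) in kg.
#' @examples
#' net_weight_to_displacement(1000, 4) # 1000 + 4 * 95
#' @export
net_weight_to_displacement <- function(net_weight_kg, capacity_persons = NULL) {
  stopifnot(is.numeric(net_weight_kg))
  if (any(is.na(net_weight_kg)) || any(net_weight_kg < 0)) {
    abort("net_weight_kg must be non-negative.")
  }
  units <- vm_units()
  per_person <- units$person_kg + units$luggage_kg
  if (is.null(capacity_persons)) {
    capacity_persons <- rep(NA_real_, length(net_weight_kg))
  }
  if (any(!is.na(capacity_persons) & capacity_persons < 0)) {
    abort("capacity_persons must be non-negative.")
  }
  cap <- ifelse(is.na(capacity_persons), 1, capacity_persons)
  net_weight_kg + per_person * cap
}
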
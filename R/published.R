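#' Load the published per-type power-law coefficients
#'
#' Returns the final per-type equations relating displacement (kg) to LOA
#' (m) as a coefficient bundle: for each of the twelve vessel types, the
#' log-scale intercept and slope with standard errors, plus the power-law
#' multiplier (`exp(intercept)`) and exponent at their printed precision.
#' With this bundle, users can estimate vessel mass without refitting the
#' regression. Standard errors are metadata only: the full coefficient
#' covariance is not part of the bundle, so no prediction intervals are
#' derived from it.
#'
#' The loader validates the schema on every load: all twelve types must be
#' present and each printed multiplier must agree with `exp(intercept)`
#' within 1% (printed-precision rounding prevents tighter agreement).
#'
#' @param path Optional path to an alternative coefficient JSON file with
#'   the same schema.
#' @return A tibble of class `coefficient_bundle` with columns
#'   `vessel_type`, `intercept`, `intercept_se`, `slope`, `slope_se`,
#'   `multiplier`, `exponent`, and attributes `version` and `provenance`.
#' @examples
#' bundle <- load_published_bundle()
#' bundle[bundle$vessel_type == "fishing", ]
#' @export
load_published_bundle <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table3_coefficients.json",
                                package = "vesselmass", mustWork = TRUE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  cols <- c("vessel_type", "intercept", "intercept_se", "slope", "slope_se",
            "multiplier", "exponent")
  if (!is.data.frame(spec$coefficients) ||
      !all(cols %in% names(spec$coefficients))) {
    abort(sprintf("Coefficient file %s does not match the bundle schema.",
                  path))
  }
  bundle <- tibble::as_tibble(spec$coefficients)[cols]
  missing <- setdiff(vessel_types(), bundle$vessel_type)
  if (length(missing) || nrow(bundle) != length(vessel_types())) {
    abort(sprintf(
      "Coefficient bundle must cover exactly the twelve vessel types; missing: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  drift <- abs(bundle$multiplier / exp(bundle$intercept) - 1)
  if (any(drift > 0.01)) {
    abort(sprintf(
      "Bundle integrity check failed: multiplier differs from exp(intercept) by > 1%% for %s.",
      paste(bundle$vessel_type[drift > 0.01], collapse = ", ")
    ))
  }
  structure(
    bundle,
    version = spec$version,
    provenance = spec$provenance,
    class = c("coefficient_bundle", class(bundle))
  )
}

#' Estimate vessel mass from the published equations
#'
#' Convenience wrapper evaluating `mass = multiplier * LOA^exponent` with
#' the published per-type coefficients — the primary entry point for users
#' who only have a vessel's type and length.
#'
#' @param vessel_type Vessel type label(s).
#' @param loa_m Length(s) overall in metres, > 0.
#' @param bundle Coefficient bundle (defaults to the packaged one).
#' @return Mass(es) in kg.
#' @examples
#' estimate_mass_published("cruise", 219.1)
#' @export
estimate_mass_published <- function(vessel_type, loa_m,
                                    bundle = load_published_bundle()) {
  predict_mass(bundle, vessel_type, loa_m)
}

#' Write a coefficient bundle back to JSON
#'
#' Inverse of [load_published_bundle()]: the written file reloads to a
#' bundle with identical values.
#'
#' @param bundle A `coefficient_bundle`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  payload <- list(
    version = attr(bundle, "version") %||% "1.0",
    provenance = attr(bundle, "provenance") %||% "",
    coefficients = as.data.frame(bundle)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
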
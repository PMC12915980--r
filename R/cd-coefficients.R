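#' Deadweight-coefficient endpoint specifications
#'
#' The deadweight coefficient C_D = DWT / displacement is tabulated in the
#' naval-architecture literature (Papanikolaou, Ship Design) as a range over
#' a span of vessel lengths for each vessel class. `cd_spec()` builds one
#' such specification; `cd_specs()` returns the four classes this package
#' relies on:
#'
#' * `large_passenger` (cruise ships): 0.23 at LOA 200 m to 0.34 at 360 m
#' * `ropax` (ferries, Ro-Ro, Ro-Pax): 0.16 at 85 m to 0.33 at 120 m
#' * `stern_trawler` (fishing vessels): 0.30 at 44 m to 0.58 at 82 m
#' * `small_passenger`: 0.15 at 50 m to 0.25 at 120 m
#'
#' @param vessel_class Text label for the class.
#' @param loa_lo_m,cd_lo Lower endpoint: LOA in metres and its C_D.
#' @param loa_hi_m,cd_hi Upper endpoint.
#' @return `cd_spec()`: a one-row tibble; `cd_specs()`: a four-row tibble
#'   keyed by `vessel_class`.
#' @examples
#' interpolate_cd(cd_specs()["large_passenger", ], 219.1)
#' @export
cd_spec <- function(vessel_class, loa_lo_m, cd_lo, loa_hi_m, cd_hi) {
  stopifnot(
    loa_lo_m < loa_hi_m,
    cd_lo > 0, cd_lo < 1,
    cd_hi > 0, cd_hi < 1
  )
  tibble::tibble(
    vessel_class = vessel_class,
    loa_lo_m = loa_lo_m, cd_lo = cd_lo,
    loa_hi_m = loa_hi_m, cd_hi = cd_hi
  )
}

#' @rdname cd_spec
#' @export
cd_specs <- function() {
  specs <- dplyr::bind_rows(
    cd_spec("large_passenger", 200, 0.23, 360, 0.34),
    cd_spec("ropax", 85, 0.16, 120, 0.33),
    cd_spec("stern_trawler", 44, 0.30, 82, 0.58),
    cd_spec("small_passenger", 50, 0.15, 120, 0.25)
  )
  out <- as.data.frame(specs)
  rownames(out) <- out$vessel_class
  out
}

#' Interpolate a deadweight coefficient at a given length
#'
#' Linearly interpolates C_D between the specification's endpoints as a
#' function of LOA. Lengths outside the endpoint span are clamped to the
#' nearer endpoint (the tabulated ranges are class-wide bounds, not trends
#' to extrapolate). The result is rounded to `decimals` places, matching
#' the precision at which such ratios are conventionally quoted.
#'
#' @param spec A one-row specification from [cd_spec()] / [cd_specs()].
#' @param loa_m Numeric vector of lengths overall in metres; must be > 0.
#' @param decimals Rounding precision (default 3). Use `Inf` for no
#'   rounding.
#' @return Numeric vector of deadweight coefficients.
#' @examples
#' interpolate_cd(cd_specs()["stern_trawler", ], c(44, 48.6, 93.4))
#' @export
interpolate_cd <- function(spec, loa_m, decimals = 3) {
  stopifnot(is.numeric(loa_m), nrow(spec) == 1)
  if (any(is.na(loa_m)) || any(loa_m <= 0)) {
    abort("loa_m must be positive and non-missing.")
  }
  x <- pmin(pmax(loa_m, spec$loa_lo_m), spec$loa_hi_m)
  cd <- spec$cd_lo +
    (x - spec$loa_lo_m) / (spec$loa_hi_m - spec$loa_lo_m) *
      (spec$cd_hi - spec$cd_lo)
  if (is.finite(decimals)) cd <- round(cd, decimals)
  cd
}
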
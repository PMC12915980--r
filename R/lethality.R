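#' Define a strike-lethality scenario grid
#'
#' A scenario is the Cartesian grid of vessel types, lengths overall and
#' transit speeds over which strike-lethality probabilities are computed,
#' together with the (constant) bow impact dimensions and an opaque whale
#' model tag. The defaults reproduce the worked demonstration: six vessel
#' types, LOA of 10, 20, 50 and 100 m, speeds of 10 and 20 kn, a flared
#' bow of 1.15 m x 1.15 m, and an adult North Atlantic right whale.
#'
#' @param vessel_types Subset of [vessel_types()].
#' @param loa_values_m Positive lengths overall in metres.
#' @param speeds_kn Positive transit speeds in knots.
#' @param impact_width_m,impact_height_m Bow impact dimensions in metres;
#'   the impact area is their product and is held constant across vessel
#'   sizes.
#' @param whale_model Opaque tag passed through to the lethality model.
#' @return An object of class `lethality_scenario`.
#' @export
lethality_scenario <- function(vessel_types = c(
                                 "container_ship", "cruise", "ferry",
                                 "pleasure_craft", "sailing", "tug"
                               ),
                               loa_values_m = c(10, 20, 50, 100),
                               speeds_kn = c(10, 20),
                               impact_width_m = 1.15,
                               impact_height_m = 1.15,
                               whale_model = "adult North Atlantic right whale") {
  vessel_types <- as_vessel_type(vessel_types)
  stopifnot(
    all(loa_values_m > 0), all(speeds_kn > 0),
    impact_width_m > 0, impact_height_m > 0
  )
  structure(
    list(
      vessel_types = vessel_types,
      loa_values_m = loa_values_m,
      speeds_kn = speeds_kn,
      impact_width_m = impact_width_m,
      impact_height_m = impact_height_m,
      whale_model = whale_model
    ),
    class = "lethality_scenario"
  )
}

#' A toy strike-lethality model for plumbing and tests
#'
#' A deliberately simple, fully documented stand-in satisfying the
#' lethality-model contract `(mass_kg, speed_m_per_s, impact_area_m2,
#' whale_model) -> probability`. It is NOT a biophysical collision model
#' and must not be used for inference; outputs are labelled "toy". The
#' functional form is a logistic in log mass and speed,
#'
#' `p = plogis(-9 + 1.2 * log10(mass_kg + 1) + 0.6 * speed_m_per_s)`,
#'
#' monotone non-decreasing in both mass and speed, with upper asymptote 1
#' as mass grows and floor `plogis(-9 + 1.2 * log10(mass_kg + 1))` at
#' speed 0. The impact area and whale tag are accepted for contract
#' compatibility but do not alter the toy's output (the bow area is
#' treated as fixed).
#'
#' @param mass_kg Vessel mass in kg, `>= 0`.
#' @param speed_m_per_s Speed in m/s, `>= 0`.
#' @param impact_area_m2 Impact area in square metres (unused).
#' @param whale_model Whale tag (unused).
#' @return Probability in (0, 1).
#' @export
toy_lethality_model <- function(mass_kg, speed_m_per_s, impact_area_m2 = 1.3225,
                                whale_model = "adult North Atlantic right whale") {
  stopifnot(all(mass_kg >= 0), all(speed_m_per_s >= 0))
  plogis(-9 + 1.2 * log10(mass_kg + 1) + 0.6 * speed_m_per_s)
}

#' Run a lethality scenario
#'
#' Evaluates the scenario grid: for every (type, LOA, speed) cell, the
#' vessel mass comes from `mass_estimator`, the speed is converted to m/s
#' (1 kn = 1.852 km/h), the impact area is width x height, and the
#' pluggable lethality model maps (mass, speed, area, whale tag) to a
#' probability. Any model satisfying the contract can be plugged in — an
#' adapter around an external biophysical collision simulation, or the
#' packaged [toy_lethality_model()] for plumbing checks.
#'
#' @param scenario A [lethality_scenario()].
#' @param mass_estimator Function `(vessel_type, loa_m) -> mass_kg`;
#'   defaults to the published power-law equations.
#' @param model Lethality model callable; defaults to
#'   [toy_lethality_model()].
#' @param model_label Label recorded in the output (default `"toy"`).
#' @return Tibble with one row per grid cell: `vessel_type`, `loa_m`,
#'   `speed_kn`, `speed_m_per_s`, `mass_kg`, `impact_area_m2`,
#'   `whale_model`, `model`, `probability`.
#' @examples
#' grid <- run_scenario(lethality_scenario())
#' nrow(grid) # 48
#' @export
run_scenario <- function(scenario = lethality_scenario(),
                         mass_estimator = NULL,
                         model = toy_lethality_model,
                         model_label = "toy") {
  stopifnot(inherits(scenario, "lethality_scenario"))
  if (is.null(mass_estimator)) {
    bundle <- load_published_bundle()
    mass_estimator <- function(vessel_type, loa_m) {
      estimate_mass_published(vessel_type, loa_m, bundle)
    }
  }
  grid <- tidyr::expand_grid(
    vessel_type = scenario$vessel_types,
    loa_m = scenario$loa_values_m,
    speed_kn = scenario$speeds_kn
  )
  grid$speed_m_per_s <- knots_to_ms(grid$speed_kn)
  grid$mass_kg <- purrr::map2_dbl(grid$vessel_type, grid$loa_m,
                                  mass_estimator)
  grid$impact_area_m2 <- scenario$impact_width_m * scenario$impact_height_m
  grid$whale_model <- scenario$whale_model
  grid$model <- model_label
  grid$probability <- purrr::pmap_dbl(
    list(grid$mass_kg, grid$speed_m_per_s, grid$impact_area_m2,
         grid$whale_model),
    function(m, v, a, w) model(m, v, a, w)
  )
  bad <- is.na(grid$probability) | grid$probability < 0 | grid$probability > 1
  if (any(bad)) {
    cells <- grid[bad, c("vessel_type", "loa_m", "speed_kn")]
    abort(sprintf(
      "Lethality model returned a value outside [0, 1] for cell(s): %s.",
      paste(sprintf("(%s, LOA %g m, %g kn)", cells$vessel_type,
                    cells$loa_m, cells$speed_kn), collapse = "; ")
    ))
  }
  grid
}

#' Plot lethality curves by vessel type
#'
#' Draws probability against LOA, one curve per vessel type, faceted by
#' speed. Requires \pkg{ggplot2}.
#'
#' @param result Output of [run_scenario()].
#' @return A ggplot object.
#' @export
plot_lethality_curves <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("Package 'ggplot2' is required for plotting.")
  }
  ggplot2::ggplot(result, ggplot2::aes(
    x = .data$loa_m, y = .data$probability, colour = .data$vessel_type
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~speed_kn, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Length overall (m)", y = "Probability of lethality",
      colour = "Vessel type"
    )
}
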
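specs <- cd_specs()

test_that("linear interpolation reproduces the quoted deadweight ratios", {
  cases <- list(
    list("large_passenger", 219.1, 0.243),
    list("ropax", 100.1, 0.233),
    list("stern_trawler", 48.6, 0.334),
    list("stern_trawler", 68.1, 0.478),
    list("small_passenger", 68.1, 0.176),
    list("stern_trawler", 93.4, 0.580), # clamped above the 82 m endpoint
    list("small_passenger", 93.4, 0.212),
    list("small_passenger", 62.2, 0.167),
    list("small_passenger", 56.3, 0.159),
    list("small_passenger", 53.2, 0.155)
  )
  for (case in cases) {
    expect_equal(
      interpolate_cd(specs[case[[1]], ], case[[2]]), case[[3]],
      info = sprintf("%s @ %g m", case[[1]], case[[2]])
    )
  }
  expect_equal(interpolate_cd(specs["stern_trawler", ], 44), 0.300)
})

test_that("interpolated C_D is monotone within range and constant outside", {
  spec <- specs["stern_trawler", ]
  loa <- seq(1, 150, by = 0.5)
  cd <- interpolate_cd(spec, loa, decimals = Inf)
  expect_true(all(diff(cd) >= 0))
  expect_true(all(cd[loa <= 44] == 0.30))
  expect_true(all(cd[loa >= 82] == 0.58))
  expect_error(interpolate_cd(spec, -1), "positive")
  expect_error(cd_spec("bad", 80, 0.3, 44, 0.6)) # endpoints out of order
})

test_that("conversion rules evaluate their functional form then the unit dialect", {
  cruise_rule <- dwt_rule("ratio", 4.1152, output_unit = "tonnes")
  expect_equal(apply_dwt_rule(cruise_rule, 10000), 41152000)

  tug_rule <- dwt_rule("power", 5.2301, exponent = 0.8752,
                       output_unit = "tonnes")
  expect_equal(apply_dwt_rule(tug_rule, 1), 5230.1)

  tanker_rule <- dwt_rule("linear", 1.1213, offset = 4773.95,
                          output_unit = "us_tons")
  expect_equal(apply_dwt_rule(tanker_rule, 0), 4773.95 * 1016)

  expect_error(apply_dwt_rule(tug_rule, -1), "non-negative")
  expect_error(dwt_rule("power", 5.2301, output_unit = "tonnes"),
               "exponent")
})

test_that("net weight converts to maximum displacement via persons capacity", {
  expect_equal(net_weight_to_displacement(1000, 4), 1380)
  expect_equal(net_weight_to_displacement(500), 595) # one-person fallback
  expect_equal(net_weight_to_displacement(500, NA), 595)
  expect_equal(net_weight_to_displacement(0, 0), 0)
  expect_error(net_weight_to_displacement(-1), "non-negative")
  expect_error(net_weight_to_displacement(10, -2), "non-negative")
})

test_that("the estimation cascade dispatches reported, net-weight and DWT routes", {
  recs <- make_records(
    c("sailing", "pleasure_craft", "cruise", "tug", "government_research"),
    loa_m = c(15, 10, 219.1, 44.1, 68.1),
    displacement_kg = c(23733, NA, NA, NA, NA),
    net_weight_kg = c(NA, 1000, NA, NA, NA),
    capacity_persons = c(NA, 4, NA, NA, NA),
    dwt_tonnes = c(NA, NA, 6059, 952, 1000)
  )
  out <- estimate_displacement(recs)
  expect_equal(out$method, c("reported", "net_weight", "dwt_ratio",
                             "dwt_equation", "dwt_mixed"))
  expect_equal(out$displacement_est_kg[1], 23733)
  expect_equal(out$displacement_est_kg[2], 1380)
  expect_equal(out$displacement_est_kg[3], 6059 * 1000 / 0.243)
  expect_equal(out$displacement_est_kg[4], 5.2301 * 952^0.8752 * 1000)
  # mixed category: three routes each converted to kg, then averaged
  mixed_oracle <- mean(c(
    1.77955 * 1000^0.975578 * 1016,
    1000 / 0.478 * 1000,
    1000 / 0.176 * 1000
  ))
  expect_equal(out$displacement_est_kg[5], mixed_oracle)

  no_mass <- make_records("tug", 40)
  expect_error(estimate_displacement(no_mass), "r001")
})

test_that("ratio strategies close the kg/tonne bookkeeping exactly", {
  strategies <- dwt_strategies()
  ratio_types <- c("cruise", "ferry", "fishing", "passenger",
                   "pleasure_craft", "sailing")
  dwt <- c(1, 7.5, 952, 6059)
  for (type in ratio_types) {
    cd <- strategies[[type]]$cd
    recs <- make_records(type, 50, dwt_tonnes = dwt)
    est <- estimate_displacement(recs)$displacement_est_kg
    expect_equal(est * cd, dwt * 1000, info = type)
    # homogeneity of degree 1 in DWT
    est2 <- estimate_displacement(
      make_records(type, 50, dwt_tonnes = 2 * dwt)
    )$displacement_est_kg
    expect_equal(est2, 2 * est, info = type)
  }
})

test_that("the ratio multipliers are reciprocal deadweight coefficients", {
  strategies <- dwt_strategies()
  ratio_types <- c("cruise", "ferry", "fishing", "passenger",
                   "pleasure_craft", "sailing")
  for (type in ratio_types) {
    s <- strategies[[type]]
    expect_equal(round(1 / s$cd, 4), s$table_multiplier, info = type)
  }
})

test_that("per-record C_D interpolation is available as an opt-in mode", {
  # a cruise ship at the upper anchor uses C_D 0.34 instead of the fixed 0.243
  recs <- make_records("cruise", 360, dwt_tonnes = 10000)
  fixed <- estimate_displacement(recs)$displacement_est_kg
  interp <- estimate_displacement(recs, cd_mode = "interpolated")$displacement_est_kg
  expect_equal(fixed, 10000 * 1000 / 0.243)
  expect_equal(interp, 10000 * 1000 / 0.34)
})

test_that("every strategy inverts: DWT recovered from displacement round-trips", {
  strategies <- dwt_strategies()
  for (type in vessel_types()) {
    mass <- if (type == "tanker") c(6e6, 5e7, 3e8) else c(2e4, 1e6, 5e7)
    dwt <- vesselmass:::invert_strategy_dwt(type, mass, strategies)
    back <- vesselmass:::strategy_mass_kg(type, dwt, strategies)
    expect_equal(back, mass, tolerance = 1e-9, info = type)
  }
  expect_error(
    vesselmass:::invert_strategy_dwt("tanker", 1, strategies),
    "below the linear rule's intercept"
  )
})
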
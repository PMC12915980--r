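quiet_fit <- function(...) {
  # noiseless fixtures trigger lm's "essentially perfect fit" warning
  suppressWarnings(fit_loglog(...))
}

test_that("noiseless power-law data is recovered exactly", {
  one <- power_law_records("tug", a = 2.5, b = log(100), seed = 11)
  fit <- quiet_fit(one)
  expect_equal(fit$coefficients$slope, 2.5, tolerance = 1e-10)
  expect_equal(fit$coefficients$intercept, log(100), tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)

  two <- power_law_records(c("ferry", "fishing"), a = c(3.0, 2.4),
                           b = c(1.0, 4.5), seed = 12)
  fit2 <- quiet_fit(two)
  co <- fit2$coefficients[match(c("ferry", "fishing"),
                                fit2$coefficients$vessel_type), ]
  expect_equal(co$slope, c(3.0, 2.4), tolerance = 1e-8)
  expect_equal(co$intercept, c(1.0, 4.5), tolerance = 1e-8)

  pw <- to_power(fit2)
  expect_equal(pw$multiplier[pw$vessel_type == "fishing"], exp(4.5),
               tolerance = 1e-8)
})

test_that("fitting preconditions are enforced with the type named", {
  thin <- make_records(c("tug", "tug", "ferry"), c(30, 30, 40),
                       displacement_kg = c(1e5, 1.2e5, 2e5))
  expect_error(fit_loglog(thin), "ferry")
  neg <- make_records(c("tug", "tug"), c(30, 40),
                      displacement_kg = c(-1, 1e5))
  expect_error(fit_loglog(neg), "> 0")
})

test_that("synthetic-fleet slopes land within 3 SE of the generating values", {
  fleet <- generate_fleet(fleet_config(sigma_log = 0.2), seed = 1)
  fit <- fit_loglog(estimate_displacement(fleet))
  gen <- load_published_bundle()
  co <- dplyr::left_join(fit$coefficients, gen, by = "vessel_type",
                         suffix = c("", "_gen"))
  expect_true(all(abs(co$slope - co$exponent) <= 3 * co$slope_se))
})

test_that("log-scale coefficients back-transform to the printed power form", {
  ct <- to_power(c(2.461, 4.459), digits = 2)
  expect_equal(ct$multiplier, 86.40)
  expect_equal(ct$exponent, 2.46)
  expect_equal(to_power(c(2.512, 4.649), digits = 2)$multiplier, 104.48)
  expect_equal(to_power(c(3.1, 0))$multiplier, 1)
})

test_that("predict_mass evaluates the power law and rejects unknown types", {
  bundle <- load_published_bundle()
  expect_equal(predict_mass(bundle, "pleasure_craft", 1), 34.47)
  expect_equal(predict_mass(bundle, "pleasure_craft", 10), 34.47 * 10^2.68)
  expect_equal(predict_mass(bundle, "fishing", 10), 0.71 * 10^3.79)
  small <- tibble::tibble(vessel_type = "tug", multiplier = 2, exponent = 1)
  expect_error(predict_mass(small, "ferry", 10), "ferry")
  expect_error(predict_mass(bundle, "tug", 0), "> 0")
})

test_that("predictions are invariant to the reference level", {
  fleet <- power_law_records(c("tug", "ferry", "fishing"),
                             a = c(2.5, 2.6, 3.8), b = c(4.6, 3.2, -0.3),
                             sigma_log = 0.2, seed = 21)
  fit <- fit_loglog(fleet)
  base_pred <- predict(fit$model)
  for (ref in levels(fit$data$vessel_type)) {
    m <- refit_with_reference(fit, ref)
    expect_equal(unname(predict(m)), unname(base_pred),
                 tolerance = 1e-10, info = ref)
  }
})

test_that("pairwise contrasts: self is null, matrices symmetric, vcov route agrees", {
  fleet <- power_law_records(c("tug", "ferry", "fishing"),
                             a = c(2.5, 2.6, 3.8), b = c(4.6, 3.2, -0.3),
                             sigma_log = 0.2, seed = 22)
  fit <- fit_loglog(fleet)
  ct <- pairwise_type_contrasts(fit)
  expect_equal(unname(diag(ct$intercept_diff)), rep(0, 3))
  expect_equal(unname(diag(ct$slope_diff)), rep(0, 3))
  expect_false(any(diag(ct$slope_significant)))
  expect_equal(ct$slope_p, t(ct$slope_p), tolerance = 1e-10)
  expect_equal(ct$intercept_p, t(ct$intercept_p), tolerance = 1e-10)

  ref <- vesselmass:::contrasts_from_vcov(fit)
  expect_equal(ct$slope_p, ref$slope_p, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ct$intercept_p, ref$intercept_p, tolerance = 1e-8,
               ignore_attr = TRUE)

  one <- quiet_fit(power_law_records("tug", 2.5, 4.6, seed = 23))
  expect_error(pairwise_type_contrasts(one), "at least two")

  # Bonferroni option only ever raises p-values
  ctb <- pairwise_type_contrasts(fit, p_adjust = "bonferroni")
  expect_true(all(ctb$slope_p >= ct$slope_p, na.rm = TRUE))
})

test_that("contrast significance calls behave under null and strong alternative", {
  null_hits <- 0L
  alt_hits <- 0L
  for (seed in 1:100) {
    null_fleet <- power_law_records(c("tug", "ferry"), a = c(2.5, 2.5),
                                    b = c(3, 3), n_per_type = 100,
                                    sigma_log = 0.2, seed = seed)
    ct0 <- pairwise_type_contrasts(fit_loglog(null_fleet))
    if (!ct0$slope_significant["tug", "ferry"] &&
          !ct0$intercept_significant["tug", "ferry"]) {
      null_hits <- null_hits + 1L
    }
    alt_fleet <- power_law_records(c("tug", "ferry"), a = c(2.0, 4.0),
                                   b = c(3, 3), n_per_type = 100,
                                   sigma_log = 0.1, seed = 1000 + seed)
    ct1 <- pairwise_type_contrasts(fit_loglog(alt_fleet))
    if (ct1$slope_significant["tug", "ferry"]) alt_hits <- alt_hits + 1L
  }
  expect_gt(null_hits, 50)  # no-difference pair mostly not flagged
  expect_gte(alt_hits, 99)  # 2-unit slope gap essentially always flagged
})

test_that("assumption diagnostics are emitted as summaries, not gates", {
  fleet <- power_law_records(c("tug", "ferry"), a = c(2.5, 2.6),
                             b = c(4.6, 3.2), sigma_log = 0.2, seed = 31)
  d <- fit_diagnostics(fit_loglog(fleet))
  expect_true("shapiro_wilk_normality" %in% d$tests$test)
  expect_true(all(d$tests$p_value >= 0 & d$tests$p_value <= 1))
  expect_equal(nrow(d$by_type), 2)
})

test_that("fits serialize to JSON and a printed-precision coefficient table", {
  fleet <- power_law_records(c("tug", "ferry"), a = c(2.5, 2.6),
                             b = c(4.6, 3.2), sigma_log = 0.1, seed = 32)
  fit <- fit_loglog(fleet)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$coefficients$slope, fit$coefficients$slope)
  expect_equal(back$adj_r_squared, fit$adj_r_squared)

  tab <- coefficient_table(fit)
  expect_equal(tab$multiplier, round(exp(tab$intercept), 2))
  expect_match(tab$equation[1], "LOA\\^")
})
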
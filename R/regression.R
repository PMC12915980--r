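#' Fit the log-log displacement regression with a type interaction
#'
#' Fits `log(displacement) ~ log(LOA) * vessel_type` by ordinary least
#' squares (natural logarithms). The interaction gives every vessel type
#' its own intercept `b` and slope `a` on the log scale, equivalent to a
#' per-type power law `displacement = exp(b) * LOA^a`. Coefficients are
#' re-expressed as absolute per-type `(a, b)` pairs with standard errors
#' (computed from the fitted covariance, independent of the treatment
#' coding's reference level), alongside the adjusted R-squared and the
#' overall F statistic.
#'
#' @param records Tibble of vessel records with a positive mass column.
#' @param mass_col Name of the mass column; defaults to
#'   `displacement_est_kg` when present, else `displacement_kg`.
#' @param alpha Significance level carried into downstream contrast tests.
#' @return An object of class `loglog_fit`: list with `model` (the `lm`),
#'   `coefficients` (tibble: `vessel_type`, `intercept`, `intercept_se`,
#'   `slope`, `slope_se`), `adj_r_squared`, `f_statistic`, `df_num`,
#'   `df_den`, `alpha`, `n` and the model `data`.
#' @seealso [to_power()], [pairwise_type_contrasts()], [fit_diagnostics()]
#' @export
fit_loglog <- function(records, mass_col = NULL, alpha = 0.05) {
  mass_col <- mass_col %||%
    if ("displacement_est_kg" %in% names(records)) "displacement_est_kg"
    else "displacement_kg"
  if (!mass_col %in% names(records)) {
    abort(sprintf("Mass column '%s' not found.", mass_col))
  }
  mass <- records[[mass_col]]
  loa <- records$loa_m
  type <- as_vessel_type(records$vessel_type)
  if (any(is.na(mass)) || any(mass <= 0)) {
    abort("All masses must be present and > 0 on the log scale.")
  }
  if (any(is.na(loa)) || any(loa <= 0)) abort("All LOA must be > 0.")

  counts <- table(type)
  distinct_loa <- tapply(loa, type, function(x) length(unique(x)))
  thin <- names(counts)[counts < 2 | distinct_loa[names(counts)] < 2]
  if (length(thin)) {
    abort(sprintf(
      "Need >= 2 records and >= 2 distinct LOA per type; offending type(s): %s.",
      paste(thin, collapse = ", ")
    ))
  }

  lev <- intersect(vessel_types(), unique(type))
  d <- data.frame(
    log_mass = log(mass),
    log_loa = log(loa),
    vessel_type = factor(type, levels = lev)
  )
  # a single-type fleet degenerates to a plain log-log line
  form <- if (length(lev) > 1) log_mass ~ log_loa * vessel_type
          else log_mass ~ log_loa
  model <- lm(form, data = d)
  coefs <- per_type_coefficients(model, lev)
  s <- summary(model)

  structure(
    list(
      model = model,
      coefficients = coefs,
      adj_r_squared = unname(s$adj.r.squared),
      f_statistic = unname(s$fstatistic[["value"]]),
      df_num = unname(s$fstatistic[["numdf"]]),
      df_den = unname(s$fstatistic[["dendf"]]),
      alpha = alpha,
      n = nrow(d),
      data = d
    ),
    class = "loglog_fit"
  )
}

# Absolute (intercept, slope) and SEs per type from one treatment-coded
# fit: for the reference level these are the base coefficients; for any
# other level the type main effect / interaction term is added, with the
# SE from the corresponding linear combination of the covariance matrix.
per_type_coefficients <- function(model, levels) {
  beta <- coef(model)
  V <- vcov(model)
  ref <- levels[1]
  rows <- lapply(levels, function(t) {
    li <- setNames(numeric(length(beta)), names(beta))
    ls <- li
    li["(Intercept)"] <- 1
    ls["log_loa"] <- 1
    if (t != ref) {
      li[paste0("vessel_type", t)] <- 1
      ls[paste0("log_loa:vessel_type", t)] <- 1
    }
    tibble::tibble(
      vessel_type = t,
      intercept = sum(li * beta),
      intercept_se = sqrt(drop(li %*% V %*% li)),
      slope = sum(ls * beta),
      slope_se = sqrt(drop(ls %*% V %*% ls))
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "Log-log displacement regression: %d records, %d vessel types\n",
    x$n, nrow(x$coefficients)
  ))
  cat(sprintf(
    "Adjusted R-squared = %.3f; F(%d, %d) = %.1f\n",
    x$adj_r_squared, x$df_num, x$df_den, x$f_statistic
  ))
  print(x$coefficients)
  invisible(x)
}

#' Refit the model with a chosen reference type
#'
#' Releveling the vessel-type factor changes the treatment coding but not
#' the fitted model: predictions are invariant, while the per-type main
#' effect and interaction terms become contrasts against the chosen
#' reference. [pairwise_type_contrasts()] uses this to test every type
#' against every other.
#'
#' @param fit A [fit_loglog()] result.
#' @param ref Canonical vessel type label to use as the reference level.
#' @return An `lm` object.
#' @export
refit_with_reference <- function(fit, ref) {
  stopifnot(inherits(fit, "loglog_fit"))
  d <- fit$data
  if (!ref %in% levels(d$vessel_type)) {
    abort(sprintf("Type '%s' not present in the fitted data.", ref))
  }
  d$vessel_type <- stats::relevel(d$vessel_type, ref = ref)
  form <- if (nlevels(d$vessel_type) > 1) log_mass ~ log_loa * vessel_type
          else log_mass ~ log_loa
  lm(form, data = d)
}

#' Convert log-scale coefficients to power-law form
#'
#' The fitted line `log(mass) = a * log(LOA) + b` back-transforms to the
#' power law `mass = exp(b) * LOA^a`: the multiplier is `exp(b)` (the mass
#' in kg of a 1-metre vessel) and the exponent is the slope `a`.
#'
#' @param x Either a `loglog_fit` or a numeric pair `c(a, b)` (slope,
#'   intercept).
#' @param digits Optional rounding applied to multiplier and exponent for
#'   display at the conventional printed precision (2 decimals); full
#'   precision is returned when `NULL` (default).
#' @param ... Unused.
#' @return For a fit: tibble with `vessel_type`, `multiplier`, `exponent`.
#'   For a pair: named list with `multiplier` and `exponent`.
#' @examples
#' to_power(c(2.461, 4.459), digits = 2) # multiplier 86.40, exponent 2.46
#' @export
to_power <- function(x, digits = NULL, ...) UseMethod("to_power")

#' @export
to_power.loglog_fit <- function(x, digits = NULL, ...) {
  out <- tibble::tibble(
    vessel_type = x$coefficients$vessel_type,
    multiplier = exp(x$coefficients$intercept),
    exponent = x$coefficients$slope
  )
  if (!is.null(digits)) {
    out$multiplier <- round(out$multiplier, digits)
    out$exponent <- round(out$exponent, digits)
  }
  out
}

#' @export
to_power.numeric <- function(x, digits = NULL, ...) {
  stopifnot(length(x) == 2, all(is.finite(x)))
  a <- x[[1]]
  b <- x[[2]]
  out <- list(multiplier = exp(b), exponent = a)
  if (!is.null(digits)) {
    out$multiplier <- round(out$multiplier, digits)
    out$exponent <- round(out$exponent, digits)
  }
  out
}

#' Predict vessel mass from LOA with power-law coefficients
#'
#' Evaluates `mass = multiplier * LOA^exponent` for the requested vessel
#' type(s). Works with any coefficient table carrying `vessel_type`,
#' `multiplier` and `exponent` columns — a [to_power()] result or the
#' published bundle from [load_published_bundle()].
#'
#' @param coeffs Coefficient table.
#' @param vessel_type Vessel type label(s).
#' @param loa_m Length(s) overall in metres, > 0. Recycled against
#'   `vessel_type`.
#' @return Mass(es) in kg.
#' @examples
#' predict_mass(load_published_bundle(), "tug", 44.1)
#' @export
predict_mass <- function(coeffs, vessel_type, loa_m) {
  stopifnot(
    all(c("vessel_type", "multiplier", "exponent") %in% names(coeffs)),
    is.numeric(loa_m)
  )
  if (any(is.na(loa_m)) || any(loa_m <= 0)) abort("loa_m must be > 0.")
  vessel_type <- as_vessel_type(vessel_type)
  idx <- match(vessel_type, coeffs$vessel_type)
  if (any(is.na(idx))) {
    abort(sprintf(
      "No coefficients for vessel type(s): %s.",
      paste(unique(vessel_type[is.na(idx)]), collapse = ", ")
    ))
  }
  coeffs$multiplier[idx] * loa_m^coeffs$exponent[idx]
}

#' Test every vessel type against every other
#'
#' The treatment-coded interaction model only tests each type against the
#' current reference level, so the model is refit with each vessel type in
#' turn as the reference and the type main-effect (intercept difference)
#' and interaction (slope difference) p-values are collected into
#' unordered-pair-symmetric matrices. No multiple-testing correction is
#' applied by default; pass `p_adjust = "bonferroni"` (or any
#' [stats::p.adjust()] method) to correct across the unique pairs.
#'
#' @param fit A [fit_loglog()] result on at least two types.
#' @param alpha Significance level; defaults to the one stored in `fit`.
#' @param p_adjust Multiple-testing correction method (default `"none"`).
#' @return An object of class `type_contrasts`: list of square matrices
#'   `intercept_diff`, `intercept_p`, `intercept_significant`,
#'   `slope_diff`, `slope_p`, `slope_significant` (diagonal: zero
#'   difference, not significant), plus `alpha` and `p_adjust`.
#' @export
pairwise_type_contrasts <- function(fit, alpha = NULL, p_adjust = "none") {
  stopifnot(inherits(fit, "loglog_fit"))
  alpha <- alpha %||% fit$alpha
  types <- levels(fit$data$vessel_type)
  k <- length(types)
  if (k < 2) abort("Pairwise contrasts need at least two vessel types.")

  mk <- function() matrix(NA_real_, k, k, dimnames = list(types, types))
  int_d <- mk(); int_p <- mk(); slo_d <- mk(); slo_p <- mk()

  for (ref in types) {
    m <- refit_with_reference(fit, ref)
    ct <- summary(m)$coefficients
    for (other in setdiff(types, ref)) {
      ic <- paste0("vessel_type", other)
      sc <- paste0("log_loa:vessel_type", other)
      int_d[ref, other] <- ct[ic, "Estimate"]
      int_p[ref, other] <- ct[ic, "Pr(>|t|)"]
      slo_d[ref, other] <- ct[sc, "Estimate"]
      slo_p[ref, other] <- ct[sc, "Pr(>|t|)"]
    }
  }
  diag(int_d) <- 0; diag(slo_d) <- 0

  adjust_sym <- function(p) {
    if (p_adjust == "none") return(p)
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    p
  }
  int_p <- adjust_sym(int_p)
  slo_p <- adjust_sym(slo_p)

  sig <- function(p) {
    s <- p < alpha
    diag(s) <- FALSE
    s
  }
  structure(
    list(
      intercept_diff = int_d, intercept_p = int_p,
      intercept_significant = sig(int_p),
      slope_diff = slo_d, slope_p = slo_p,
      slope_significant = sig(slo_p),
      alpha = alpha, p_adjust = p_adjust
    ),
    class = "type_contrasts"
  )
}

# Covariance-based computation of the same contrasts from a single fit;
# kept as an internal cross-check of the releveling route.
contrasts_from_vcov <- function(fit) {
  beta <- coef(fit$model)
  V <- vcov(fit$model)
  df <- fit$model$df.residual
  types <- levels(fit$data$vessel_type)
  ref <- types[1]
  term <- function(t, slope) {
    nm <- setNames(numeric(length(beta)), names(beta))
    if (t != ref) {
      nm[paste0(if (slope) "log_loa:vessel_type" else "vessel_type", t)] <- 1
    }
    nm
  }
  k <- length(types)
  int_p <- matrix(NA_real_, k, k, dimnames = list(types, types))
  slo_p <- int_p
  for (a in types) for (b in setdiff(types, a)) {
    for (slope in c(FALSE, TRUE)) {
      l <- term(a, slope) - term(b, slope)
      est <- sum(l * beta)
      se <- sqrt(drop(l %*% V %*% l))
      p <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
      if (slope) slo_p[a, b] <- p else int_p[a, b] <- p
    }
  }
  list(intercept_p = int_p, slope_p = slo_p)
}

#' Residual diagnostics for a fitted log-log regression
#'
#' Emits the standard assumption checks — Shapiro-Wilk on the residuals
#' (normality), a Breusch-Pagan test (homogeneity, when \pkg{lmtest} is
#' available) and per-type residual spread — as a summary table. These are
#' diagnostics for the analyst to inspect, not pass/fail gates.
#'
#' @param fit A [fit_loglog()] result.
#' @return A list with `tests` (tibble of test statistics and p-values)
#'   and `by_type` (tibble of per-type residual mean and SD).
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "loglog_fit"))
  res <- stats::residuals(fit$model)
  tests <- tibble::tibble(test = character(), statistic = numeric(),
                          p_value = numeric())
  if (length(res) >= 3 && length(res) <= 5000) {
    sw <- shapiro.test(res)
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      test = "shapiro_wilk_normality",
      statistic = unname(sw$statistic), p_value = sw$p.value
    ))
  }
  if (requireNamespace("lmtest", quietly = TRUE)) {
    bp <- lmtest::bptest(fit$model)
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      test = "breusch_pagan_homogeneity",
      statistic = unname(bp$statistic), p_value = bp$p.value
    ))
  }
  by_type <- tibble::tibble(
    vessel_type = fit$data$vessel_type,
    residual = res
  ) |>
    dplyr::group_by(.data$vessel_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_residual = mean(.data$residual),
      sd_residual = stats::sd(.data$residual),
      .groups = "drop"
    )
  list(tests = tests, by_type = by_type)
}

#' Serialize a fit to JSON and a coefficient table to CSV
#'
#' `write_fit_json()` stores the per-type log-scale coefficients with
#' standard errors plus the fit summary statistics; `coefficient_table()`
#' builds the displayable per-type table combining log-scale and power-law
#' forms (power-law columns rounded to 2 decimals, the conventional
#' printed precision).
#'
#' @param fit A [fit_loglog()] result.
#' @param path Output path.
#' @return `write_fit_json()`: `path`, invisibly. `coefficient_table()`:
#'   a tibble.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "loglog_fit"))
  payload <- list(
    coefficients = fit$coefficients,
    adj_r_squared = fit$adj_r_squared,
    f_statistic = fit$f_statistic,
    df_num = fit$df_num,
    df_den = fit$df_den,
    alpha = fit$alpha,
    n = fit$n
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
coefficient_table <- function(fit) {
  stopifnot(inherits(fit, "loglog_fit"))
  pw <- to_power(fit, digits = 2)
  dplyr::left_join(fit$coefficients, pw, by = "vessel_type") |>
    dplyr::mutate(
      equation = sprintf("mass_kg = %.2f * LOA^%.2f",
                         .data$multiplier, .data$exponent)
    )
}
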
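# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# A minimal valid record tibble; any field can be overridden per record.
make_records <- function(vessel_type, loa_m, dwt_tonnes = NA_real_,
                         displacement_kg = NA_real_,
                         net_weight_kg = NA_real_,
                         capacity_persons = NA_real_,
                         source = "ais", record_id = NULL) {
  n <- max(lengths(list(vessel_type, loa_m, dwt_tonnes, displacement_kg)))
  tibble::tibble(
    record_id = record_id %||% sprintf("r%03d", seq_len(n)),
    vessel_type = rep_len(vessel_type, n),
    loa_m = as.numeric(rep_len(loa_m, n)),
    dwt_tonnes = as.numeric(rep_len(dwt_tonnes, n)),
    displacement_kg = as.numeric(rep_len(displacement_kg, n)),
    net_weight_kg = as.numeric(rep_len(net_weight_kg, n)),
    capacity_persons = as.numeric(rep_len(capacity_persons, n)),
    source = rep_len(source, n)
  )
}

# Records drawn exactly from per-type power laws mass = exp(b) * LOA^a
# (optionally with log-normal noise), reported as displacement_kg so they
# feed straight into fit_loglog.
power_law_records <- function(types, a, b, n_per_type = 50,
                              sigma_log = 0, seed = NULL,
                              loa_range = c(5, 200)) {
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::pmap(list(types, a, b), function(type, ai, bi) {
    loa <- exp(runif(n_per_type, log(loa_range[1]), log(loa_range[2])))
    mass <- exp(bi) * loa^ai * exp(rnorm(n_per_type, 0, sigma_log))
    make_records(type, loa, displacement_kg = mass, source = "online",
                 record_id = sprintf("%s_%03d", type, seq_len(n_per_type)))
  })
  dplyr::bind_rows(rows)
}

write_fleet_csv <- function(records, path = withr::local_tempfile(
                              fileext = ".csv",
                              .local_envir = parent.frame())) {
  readr::write_csv(records, path, progress = FALSE)
  path
}

`%||%` <- rlang::`%||%`
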
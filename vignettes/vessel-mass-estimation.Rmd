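---
title: "Estimating vessel displacement from length overall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vessel displacement from length overall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmass)
```

## The problem

Biophysical models of whale-ship collisions need three vessel parameters:
transit speed, bow impact area and total mass. Speed comes from dynamic AIS
(Automatic Identification System) broadcasts and impact area can be
generalised by bow shape, but a vessel's total mass — its *displacement*,
the mass of water the hull displaces — is reported almost nowhere: not in
AIS static data, and rarely in public vessel specifications. What AIS static
data does carry is the length overall (LOA, metres) and, for larger
commercial vessels, the maximum deadweight tonnage (DWT, tonnes): the mass
of cargo, fuel, crew, passengers, provisions and non-permanent ballast.
Displacement is the sum of DWT and the light-ship weight of the empty hull.
Gross tonnage, despite its name, is a volume measure and is deliberately
ignored here.

`vesselmass` closes that gap in two stages:

1. **Training-set construction.** Convert whatever mass proxy a record
   carries (DWT, net weight, or a directly reported displacement) into a
   displacement in kg, using type-specific naval-architecture conversion
   strategies.
2. **Regression.** Fit `log(displacement) ~ log(LOA) * vessel_type` and
   back-transform each type's line into a power law
   `displacement = exp(b) * LOA^a`, so that downstream users need nothing
   but a vessel's type and length.

The fitted per-type equations are shipped as a loadable coefficient bundle,
and a harness feeds the resulting masses into any strike-lethality model
that satisfies a simple callable contract.

## Converting a mass proxy to displacement

`estimate_displacement()` dispatches each record through a fixed cascade:
a reported displacement is used as-is; otherwise a reported net (light-ship)
weight is corrected upward by 95 kg — one average person (75 kg) plus one
piece of luggage (20 kg) — per berth of the vessel's maximum persons
capacity (one person when the capacity is unknown); otherwise the record's
DWT is converted by the vessel type's strategy:

* **Explicit equations** (bulk carrier, container ship, tanker, tug): a
  published linear or power relation between DWT and displacement. The bulk
  carrier, container ship and tanker equations yield U.S. customary tons
  (1016 kg, the long ton); their output is converted to kg with that
  factor, while the tug equation yields tonnes. The source tables do not
  state the input dialect; DWT is fed in as reported (tonnes) and only the
  output unit is interpreted, matching the workflow the training set was
  built with.
* **Deadweight-coefficient ratios** (cruise, ferry, fishing, passenger,
  pleasure craft, sailing): displacement = DWT / C_D, where the deadweight
  coefficient C_D = DWT/displacement is tabulated per vessel class as a
  range over a span of lengths. The package interpolates C_D linearly
  between the tabulated endpoints and clamps outside the span; linear
  interpolation reproduces every conventionally quoted ratio for these
  classes to 3 decimals, which we take as confirmation of the form, and
  the clamping choice is fixed by the quoted value 0.580 at LOA ≈ 93 m
  coinciding with the 82 m endpoint value. By default each type uses one
  fixed C_D anchored at its reference sample's average LOA (0.243, 0.233,
  0.334, 0.167, 0.159, 0.155); `cd_mode = "interpolated"` re-interpolates
  per record instead, as an opt-in.
* **Mixed categories** (government/research, "other"): these buckets span
  heterogeneous designs, so three estimates — the container-ship equation,
  the stern-trawler ratio and the small-passenger ratio evaluated at the
  bucket's average LOA — are each converted to kg and then averaged without
  weights. Conversion precedes averaging; with mixed unit dialects the
  order matters.

```{r cascade}
fleet <- tibble::tibble(
  record_id = c("a", "b", "c"),
  vessel_type = c("cruise", "sailing", "tug"),
  loa_m = c(219.1, 12, 44.1),
  dwt_tonnes = c(6059, NA, 952),
  displacement_kg = NA_real_,
  net_weight_kg = c(NA, 4000, NA),
  capacity_persons = c(NA, 6, NA),
  source = c("ais", "online", "ais")
)
estimate_displacement(fleet)[, c("record_id", "displacement_est_kg", "method")]
```

Duplicate listings of the same vessel model — identical type, LOA and DWT —
are collapsed by `dedupe_fleet()` before fitting; the first occurrence in
file order is kept (an arbitrary but deterministic convention, since
replicates are interchangeable for the regression).

## The regression model

`fit_loglog()` fits, by ordinary least squares with natural logarithms,

$$\log(\Delta_i) = a_{t(i)} \log(\mathrm{LOA}_i) + b_{t(i)} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

a full interaction of log-LOA with vessel type: every type gets its own
elasticity (slope) and intercept, while a common residual variance is
pooled across types. Natural logs are required for the back-transform
`multiplier = exp(b)` to reproduce the published multipliers. The per-type
coefficients and standard errors are derived from the fitted covariance
matrix, so they do not depend on which type happens to be the treatment
coding's reference level. `to_power()` converts a fit (or a single `(a, b)`
pair) to the power-law form; full precision is carried internally and
2-decimal rounding is display-only.

Multiplicative (log-normal) errors are the natural choice here: vessel
masses span seven orders of magnitude, and hull-design variability scales
with size. The model assumes within-type log-linearity and a shared error
variance across types; `fit_diagnostics()` emits Shapiro-Wilk and
Breusch-Pagan summaries plus per-type residual spread so the analyst can
inspect those assumptions — they are reported, never used as gates.

**Type comparisons.** The interaction parameterisation only tests each type
against the reference level, so `pairwise_type_contrasts()` literally
refits the model with every type as the reference in turn and collects the
intercept- and slope-difference p-values into symmetric matrices. Refitting
changes the coding, not the model: predictions are invariant to the
reference level (a tested property), and an internal covariance-based
computation of the same contrasts is required to agree with the releveled
route. No multiple-testing correction is applied by default — the contrast
matrix is descriptive, guiding users who want to pool statistically
indistinguishable types — but any `stats::p.adjust` method (e.g. Bonferroni)
can be switched on.

At significance level α = 0.05 (the default, stored in the fit), every
vessel type in the reference sample differed from at least one other type,
which is why twelve separate equations are shipped rather than a pooled
one.

## The published coefficient bundle

`load_published_bundle()` returns the final per-type equations — log-scale
intercept and slope with standard errors, plus printed-precision multiplier
and exponent — validated on every load (all twelve types present;
`multiplier` within 1% of `exp(intercept)`, the slack printed-precision
rounding requires). The standard errors are exposed as metadata only: the
full coefficient covariance is not part of the bundle, so prediction
intervals are deliberately not offered from it.

```{r bundle}
estimate_mass_published("pleasure_craft", c(10, 20, 50))
```

These are *maximum* masses (the training DWT values are maxima) and are
intended as realistic risk-model inputs, not naval-architecture quantities:
they must not be used for ship design, where beam, draught and block
coefficient matter.

## The synthetic fleet generator

Real AIS extracts cannot be redistributed, so `generate_fleet()` produces
fleets with the statistical structure of the 873-vessel reference sample,
making the fitting, contrast and harness code fully testable offline:

* **Composition**: the per-type AIS/online counts of
  `default_fleet_table()` (summing to 873).
* **LOA**: truncated normal per type, parameterised directly by the
  reference sample's mean, SD and observed range, sampled by inverse CDF.
  The summaries are all the information available, so truncated-normal is
  a stand-in family; for small types the truncation is heavy and the
  realised mean sits above the parent mean, which the tests account for
  with the closed-form truncated moments.
* **Mass**: `multiplier * LOA^exponent * exp(e)` with
  `e ~ N(0, sigma_log^2)`, generating coefficients defaulting to the
  published bundle. The default `sigma_log = 0.2` is a modelling choice
  producing dispersion consistent with the reference fit's high
  R-squared regime (≈ 0.99 at these sizes), not an estimated value.
* **Observables**: AIS-sourced records report a DWT obtained by inverting
  the type's conversion strategy at the generated mass (ratios, powers and
  linear forms invert analytically; the mixed average is solved by
  root-finding on the log-DWT scale to ~1e-13 relative), so the estimation
  cascade recovers the generated mass exactly; online-sourced records
  report the displacement directly.

With `sigma_log = 0`, a refit recovers the generating coefficients to
numerical precision (≤ 1e-8, in practice ~1e-14) — the round-trip that
pins down both the generator and the estimation cascade. With
`sigma_log = 0.2` at the default sizes, all twelve refit slopes fall
within ±3 reported SE of the generating exponents in about 97 of 100
seeds (per-type 3-SE coverage ≈ 0.997, jointly ≈ 0.967 across twelve
types). Test and acceptance runs use fleets of the default 873 records
and ensembles of 100 seeds, which keeps the full suite under a minute.
Synthetic fleets do not emulate regional or construction-year structure,
nor real AIS quirks (transcription errors, unit mix-ups, type
mislabelling), so passing tests demonstrate the statistical machinery,
not robustness to dirty field data.

## The lethality harness

`run_scenario()` reproduces the intended application pattern end to end:
a grid of vessel types × LOA × speeds, mass from the published equations,
speed converted at 1 kn = 1.852 km/h, a constant flared-bow impact area
(1.15 m × 1.15 m by default), and a pluggable lethality model with
signature `(mass_kg, speed_m_per_s, impact_area_m2, whale_model) ->
probability`. The default scenario is six types (container ship, cruise,
ferry, pleasure craft, sailing, tug) × LOA {10, 20, 50, 100} m × {10, 20}
kn — 48 cells — with an adult North Atlantic right whale tag.

The external biophysical collision model is integrated *only* through that
contract: this package never reimplements it, and no quantitative lethality
claims are made here. `toy_lethality_model()` is a documented logistic in
log mass and speed, monotone and bounded in (0, 1), used to verify the
plumbing (grid completeness, contract enforcement, monotonicity
propagation); its outputs are labelled `"toy"` and carry no biological
meaning. Because displacement increases with LOA for every type, any
mass-monotone model yields probabilities non-decreasing in LOA within a
(type, speed) cell — a property the tests check — while vessels of equal
length but different types receive different masses and hence different
probabilities, the behaviour that motivates type-specific equations.

## Numerical and design notes

* **Rounding.** Interpolated deadweight coefficients are rounded to 3
  decimals (the convention for quoted ratios); power-law coefficients are
  rounded to 2 decimals for display only.
* **Degenerate inputs.** A single-type fleet degenerates to a plain
  log-log line; fitting requires ≥ 2 records and ≥ 2 distinct LOA per type
  and strictly positive masses and lengths; DWT must be non-negative; a
  tanker displacement below the linear rule's intercept cannot be
  inverted and is an error.
* **Validation posture.** Rows failing record invariants are dropped with
  a warning naming them and returned as a problems table, never silently;
  LOA outside [3 m, 450 m] warns but does not reject.
* **Determinism.** All generator randomness flows from one user-visible
  seed; the CLI logs version, config hash and seed for every run.
* **Limitations.** The equations estimate maximum displacement, aggregate
  heterogeneous designs into twelve buckets, ignore region and
  construction year, and have not been validated against measured
  displacements; they are inputs for strike-risk screening, not
  engineering values.
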
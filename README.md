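# vesselmass

Estimate a vessel's displacement (total mass) from its length overall and
type, for use in whale-ship strike risk models.

## Why

Biophysical models of whale-ship collisions take a vessel's speed, bow
impact area and total mass, and return a probability that a strike is
lethal. Speed and bow shape are easy to obtain; total mass is not: AIS
(Automatic Identification System) static data reports a vessel's length
overall (LOA, m) and, for larger commercial vessels, its maximum deadweight
tonnage (DWT, tonnes), but never its displacement Δ — the mass of water the
hull displaces, i.e. the vessel's total mass. This package is for marine
conservation scientists and risk-assessment practitioners who need a
defensible mass estimate from the data they actually have.

`vesselmass` provides:

* the naval-architecture conversion strategies that turn a DWT, a net
  (light-ship) weight, or a reported displacement into Δ in kg — deadweight
  coefficient (C_D = DWT/Δ) interpolation, published linear/power
  equations with their unit dialects (metric tonne = 1000 kg, U.S. ton =
  1016 kg), and a persons-capacity correction (75 kg person + 20 kg
  luggage per berth);
* the regression at the core of the method: a log-log linear model with a
  vessel-type interaction,

  `log(Δ) = a·log(LOA) + b` per type, back-transformed to the power law
  `Δ = exp(b) · LOA^a`,

  with releveling-based all-pairs type contrasts;
* a loadable bundle of the final per-type coefficients for all twelve
  vessel types (bulk carrier, container ship, cruise, ferry, fishing,
  government/research, other, passenger, pleasure craft, sailing, tanker,
  tug), so mass estimation needs no refitting;
* a seeded synthetic-fleet generator reproducing the 873-vessel reference
  sample's composition, for offline testing and parameter-recovery checks;
* a harness that feeds estimated masses to any strike-lethality model
  implementing the contract `(mass_kg, speed_m_per_s, impact_area_m2,
  whale_model) -> probability`, plus a command-line interface
  (`inst/cli/vesselmass.R`).

## Worked example

Mass from type and length, via the published equations:

```r
library(vesselmass)
estimate_mass_published(c("tug", "fishing", "container_ship"), c(30, 30, 300))
#> [1]    532853    281545 107209194   # kg (rounded)
```

A 30 m tug masses ~533 t while a 30 m fishing vessel masses ~282 t — same
length, different design, roughly a factor-2 mass difference, which is the
point of type-specific equations. The 300 m container ship comes out at
~107 000 t.

Building displacements from raw records (the training-set operations):

```r
fleet <- tibble::tibble(
  record_id = c("a", "b"), vessel_type = c("cruise", "sailing"),
  loa_m = c(219.1, 12), dwt_tonnes = c(6059, NA),
  displacement_kg = NA_real_, net_weight_kg = c(NA, 4000),
  capacity_persons = c(NA, 6), source = c("ais", "online")
)
estimate_displacement(fleet)[, c("record_id", "displacement_est_kg", "method")]
#>   record_id displacement_est_kg method
#> 1 a                   24934156.  dwt_ratio    # 6059 t / C_D 0.243, in kg
#> 2 b                       4570   net_weight   # 4000 + 6 x (75 + 20) kg
```

Feeding masses to a (toy) lethality model over the demonstration grid — six
vessel types × LOA {10, 20, 50, 100} m × {10, 20} kn, constant 1.15 m ×
1.15 m flared-bow impact area:

```r
grid <- run_scenario(lethality_scenario())
head(grid[, c("vessel_type", "loa_m", "speed_kn", "mass_kg", "probability")], 4)
#>   vessel_type    loa_m speed_kn mass_kg probability
#> 1 container_ship    10       10  24918.      0.346
#> 2 container_ship    10       20  24918.      0.921
#> 3 container_ship    20       10 137103.      0.562
#> 4 container_ship    20       20 137103.      0.966
```

The probabilities come from `toy_lethality_model()` — a documented,
monotone logistic stand-in for plumbing checks, not a biophysical model;
substitute your own model function to get scientific numbers.

To refit the regression yourself (e.g. on your own fleet or a synthetic
one): `fit_loglog()`, `to_power()`, `pairwise_type_contrasts()` and
`fit_diagnostics()`; see `vignette("vessel-mass-estimation")` for the
model, its assumptions and the design choices.

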
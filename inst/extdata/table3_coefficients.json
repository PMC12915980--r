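{
  "version": "1.0",
  "provenance": "Per-type power-law coefficients from a log-log regression of vessel displacement (kg) on length overall (m) with a vessel-type interaction, fitted to an 873-vessel reference sample (twelve types). Intercept/slope are on the natural-log scale with standard errors; multiplier = exp(intercept) and exponent = slope at printed precision.",
  "coefficients": [
    {"vessel_type": "bulk_carrier",        "intercept": 1.729,  "intercept_se": 1.117, "slope": 3.058, "slope_se": 0.208, "multiplier": 5.64,   "exponent": 3.06},
    {"vessel_type": "container_ship",      "intercept": 4.459,  "intercept_se": 0.917, "slope": 2.461, "slope_se": 0.168, "multiplier": 86.40,  "exponent": 2.46},
    {"vessel_type": "cruise",              "intercept": 4.580,  "intercept_se": 0.786, "slope": 2.281, "slope_se": 0.147, "multiplier": 97.51,  "exponent": 2.28},
    {"vessel_type": "ferry",               "intercept": 3.225,  "intercept_se": 0.691, "slope": 2.619, "slope_se": 0.153, "multiplier": 25.15,  "exponent": 2.62},
    {"vessel_type": "fishing",             "intercept": -0.344, "intercept_se": 0.185, "slope": 3.785, "slope_se": 0.061, "multiplier": 0.71,   "exponent": 3.79},
    {"vessel_type": "government_research", "intercept": 1.083,  "intercept_se": 0.455, "slope": 3.217, "slope_se": 0.112, "multiplier": 2.95,   "exponent": 3.22},
    {"vessel_type": "other",               "intercept": 0.973,  "intercept_se": 0.364, "slope": 3.354, "slope_se": 0.085, "multiplier": 2.64,   "exponent": 3.35},
    {"vessel_type": "passenger",           "intercept": 1.463,  "intercept_se": 0.358, "slope": 3.081, "slope_se": 0.122, "multiplier": 4.32,   "exponent": 3.08},
    {"vessel_type": "pleasure_craft",      "intercept": 3.540,  "intercept_se": 0.261, "slope": 2.685, "slope_se": 0.073, "multiplier": 34.47,  "exponent": 2.68},
    {"vessel_type": "sailing",             "intercept": 0.2082, "intercept_se": 0.298, "slope": 3.529, "slope_se": 0.106, "multiplier": 1.23,   "exponent": 3.53},
    {"vessel_type": "tanker",              "intercept": 1.981,  "intercept_se": 1.154, "slope": 3.032, "slope_se": 0.219, "multiplier": 7.25,   "exponent": 3.03},
    {"vessel_type": "tug",                 "intercept": 4.649,  "intercept_se": 0.508, "slope": 2.512, "slope_se": 0.136, "multiplier": 104.48, "exponent": 2.51}
  ]
}
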
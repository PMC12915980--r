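{
  "version": "1.0",
  "provenance": "Deadweight-to-displacement conversion strategies assembled from naval-architecture sources: Papanikolaou, Ship Design (Table 2.1 and appendices), Kalokairinos et al., and IHS Fairplay. Ratio strategies use a fixed deadweight coefficient anchored at the reference sample's average LOA for that type.",
  "strategies": {
    "bulk_carrier": {
      "kind": "rule", "form": "power", "scale": 2.21442,
      "exponent": 0.943855, "output_unit": "us_tons",
      "source_label": "Kalokairinos et al."
    },
    "container_ship": {
      "kind": "rule", "form": "power", "scale": 1.77955,
      "exponent": 0.975578, "output_unit": "us_tons",
      "source_label": "Kalokairinos et al."
    },
    "cruise": {
      "kind": "ratio", "cd": 0.243, "cd_class": "large_passenger",
      "anchor_loa_m": 219.1, "table_multiplier": 4.1152,
      "source_label": "Papanikolaou"
    },
    "ferry": {
      "kind": "ratio", "cd": 0.233, "cd_class": "ropax",
      "anchor_loa_m": 100.1, "table_multiplier": 4.2918,
      "source_label": "Papanikolaou"
    },
    "fishing": {
      "kind": "ratio", "cd": 0.334, "cd_class": "stern_trawler",
      "anchor_loa_m": 48.6, "table_multiplier": 2.9940,
      "source_label": "IHS Fairplay"
    },
    "government_research": {
      "kind": "mixed", "cd_fishing": 0.478, "cd_small_passenger": 0.176,
      "anchor_loa_m": 68.1,
      "source_label": "container-ship equation averaged with stern-trawler and small-passenger ratios"
    },
    "other": {
      "kind": "mixed", "cd_fishing": 0.580, "cd_small_passenger": 0.212,
      "anchor_loa_m": 93.4,
      "source_label": "container-ship equation averaged with stern-trawler and small-passenger ratios"
    },
    "passenger": {
      "kind": "ratio", "cd": 0.167, "cd_class": "small_passenger",
      "anchor_loa_m": 62.2, "table_multiplier": 5.988,
      "source_label": "Papanikolaou"
    },
    "pleasure_craft": {
      "kind": "ratio", "cd": 0.159, "cd_class": "small_passenger",
      "anchor_loa_m": 56.3, "table_multiplier": 6.2893,
      "source_label": "Papanikolaou"
    },
    "sailing": {
      "kind": "ratio", "cd": 0.155, "cd_class": "small_passenger",
      "anchor_loa_m": 53.2, "table_multiplier": 6.4516,
      "source_label": "Papanikolaou"
    },
    "tanker": {
      "kind": "rule", "form": "linear", "scale": 1.1213,
      "offset": 4773.95, "output_unit": "us_tons",
      "source_label": "Kalokairinos et al."
    },
    "tug": {
      "kind": "rule", "form": "power", "scale": 5.2301,
      "exponent": 0.8752, "output_unit": "tonnes",
      "source_label": "IHS Fairplay"
    }
  }
}
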
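{
  "package": "repeatscape",
  "version": "0.1.0",
  "seed": 424242,
  "config_hash": "22b8d0a2e97e46e0fd57d08b4d0fe06f",
  "species": ["species_A", "species_B"],
  "n_panel_probes": 2,
  "parameters": {
    "thresholds": {
      "min_identity": 0.8,
      "min_overlap_bp": 100
    },
    "microsat": {
      "unit_min": 2,
      "unit_max": 4,
      "min_units": 3
    }
  }
}
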
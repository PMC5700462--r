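{
  "note": "Literature-derived reference values for hairpin-DNA hybridization with the four target alleles: destination-resolved transition probabilities and mean lifetimes, per-device state occupancies from five representative recordings, device current levels, and duplex/hairpin melting temperatures. These are published summary statistics, not measured by this package.",
  "states": ["low", "intermediate", "high"],
  "kinetics": {
    "WT-C": {
      "P": [[0, 0.856, 0.144], [0.774, 0, 0.226], [0.191, 0.809, 0]],
      "tau_ms": [[null, 18.45, 25.03], [1.69, null, 3.36], [0.86, 0.55, null]],
      "levels_nA": [-3.09, 0, 3.19]
    },
    "MT-A": {
      "P": [[0, 0.697, 0.303], [0.386, 0, 0.614], [0.166, 0.834, 0]],
      "tau_ms": [[null, 8.97, 2.36], [47.16, null, 49.16], [3.00, 8.13, null]],
      "levels_nA": [-1.35, 0, 1.36]
    },
    "MT-G": {
      "P": [[0, 0.803, 0.197], [0.164, 0, 0.836], [0.177, 0.823, 0]],
      "tau_ms": [[null, 13.02, 5.66], [32.93, null, 43.30], [2.63, 6.58, null]],
      "levels_nA": [-1.21, 0, 1.33]
    },
    "MT-T": {
      "P": [[0, 0.597, 0.403], [0.225, 0, 0.775], [0.035, 0.965, 0]],
      "tau_ms": [[null, 2.89, 2.14], [44.86, null, 45.64], [3.12, 4.73, null]],
      "levels_nA": [-1.38, 0, 1.25]
    }
  },
  "occupancy_avg": {
    "WT-C": {"mean": [78.5, 20.2, 1.3], "sd": [1.8, 1.8, 0.6]},
    "MT-A": {"mean": [3.6, 90.0, 6.4], "sd": [1.2, 0.8, 0.6]},
    "MT-G": {"mean": [8.3, 72.0, 19.7], "sd": [1.8, 2.6, 1.8]},
    "MT-T": {"mean": [1.6, 90.5, 7.9], "sd": [0.1, 1.0, 1.0]}
  },
  "occupancy_devices": {
    "WT-C": {
      "low": [76.2, 79.6, 81.3, 79.2, 76.4],
      "intermediate": [21.7, 19.3, 17.9, 18.9, 23.1],
      "high": [2.1, 1.1, 0.8, 1.9, 0.5]
    },
    "MT-A": {
      "low": [1.2, 3.5, 4.2, 4.9, 4.2],
      "intermediate": [90.4, 90.0, 89.6, 88.8, 90.8],
      "high": [8.4, 6.5, 6.2, 6.3, 5.0]
    },
    "MT-G": {
      "low": [6.3, 5.2, 9.0, 8.1, 11.7],
      "intermediate": [70.6, 78.5, 72.5, 71.4, 68.5],
      "high": [23.1, 16.3, 18.5, 20.5, 19.8]
    },
    "MT-T": {
      "low": [1.6, 1.5, 1.4, 1.6, 1.7],
      "intermediate": [92.7, 90.6, 88.4, 90.0, 90.8],
      "high": [5.7, 7.9, 10.2, 8.4, 7.5]
    }
  },
  "tm_C": {"hairpin": 46.5, "duplex_wt": 59.6},
  "hairpin_sequence": "TGAGGATGGATAGATGCTTGCCTCA",
  "stem_length": 5
}
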
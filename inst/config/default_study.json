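{
  "chromosome": "URA3",
  "n_cells": 100,
  "frames": 50,
  "dt": 30,
  "seed": 1,
  "localization_sd": 0,
  "include_positions": false,
  "mc_anchor": 60,
  "mc_per": 80,
  "schedule": [
    {"stage": "T0", "t_hours": 0, "mu": 0.00, "p_rabl": 1.0000, "D0": 0.015},
    {"stage": "T1", "t_hours": 1, "mu": 0.00, "p_rabl": 0.5461, "D0": 0.020},
    {"stage": "T2", "t_hours": 2, "mu": 0.00, "p_rabl": 0.2982, "D0": 0.025},
    {"stage": "T3", "t_hours": 3, "mu": 0.08, "p_rabl": 0.1629, "D0": 0.030},
    {"stage": "T4", "t_hours": 4, "mu": 1.27, "p_rabl": 0.0889, "D0": 0.035},
    {"stage": "T5", "t_hours": 5, "mu": 3.36, "p_rabl": 0.0486, "D0": 0.040}
  ]
}
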
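{
  "simulation": {
    "seed": 1,
    "duration_h": 24,
    "frame_interval_h": 0.25,
    "field_size_um": [256, 256, 64],
    "n_cells_per_mode": 100,
    "vessel_n_segments": 200,
    "vessel_radius_um": 2,
    "vessel_radial_bias": 0.7,
    "noise_sd": 1
  },
  "analysis": {
    "speed_gate_umh": 10,
    "motility_displacement_um": 20,
    "min_on_vessel_h": 5,
    "traceability_min_h": 10,
    "association_threshold_um": 5,
    "z_exclusion_um": 15,
    "xy_margin_um": 20,
    "size_filter_um3": 6000,
    "n_bins": 4
  }
}
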
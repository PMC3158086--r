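{
  "version": 1,
  "pixel_size_um": 2,
  "field_size_um": [1500, 1500],
  "nodules_per_well": 14,
  "diameter_range_um": [50, 400],
  "core_fraction": 0.55,
  "min_gap_um": 4,
  "wells_per_condition": 3,
  "dose_response": {
    "d50_J_cm2": 19.37694501,
    "hill": 2.5,
    "irr_scale_mW_cm2": 60,
    "irr_hill": 3,
    "core_efficiency": 1,
    "hypoxia_factor": 1.5,
    "size_ref_um": 200,
    "size_gamma": 0.25,
    "reference_irradiance": 25,
    "penetration_depth_um": 125
  },
  "noise": {
    "photon_scale": 10,
    "read_sigma": 3,
    "background_level": 100
  },
  "brightness": {
    "live": 3000,
    "dead": 3000,
    "uptake": 3000,
    "pi": 3000,
    "apotrace": 3000
  },
  "ph_profile": {
    "ph_core": 5.6,
    "ph_edge": 7.2,
    "exponent": 2
  },
  "snarf": {
    "pka": 6.4,
    "acid_peak_nm": 580,
    "base_peak_nm": 640,
    "sigma_nm": 30,
    "brightness": 2000
  },
  "uptake": {
    "decay_length_um": 125,
    "tau": 1,
    "trapping_s": 0.5,
    "apoptotic_fraction": 0.97
  },
  "pipeline": {
    "min_diameter_um": 30,
    "low_signal_factor": 5,
    "plateau_tol": 0.02
  }
}
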
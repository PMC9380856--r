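{
  "description": "Default three-group cohort configuration. Group-level means/SDs of the lentiform nucleus indices (mm, mm^2, signal units). asymmetry_delta (short line) and asymmetry_delta_sisd (intensity SD) are calibrated as twice the gap between the side-mean and corrected-index group means, so corrected indices reproduce their published levels; the deltas themselves are a generator assumption.",
  "groups": [
    {
      "group_label": "MSA-P",
      "n_subjects": 19,
      "means": {"SL": 5.07, "LL": 14.97, "area": 146.78, "SIm_LN": 698.13, "SIsd_LN": 164.13, "SIm_CSF": 1066.31, "SIsd_CSF": 49.02},
      "sds":   {"SL": 1.86, "LL": 2.85,  "area": 49.30,  "SIm_LN": 434.11, "SIsd_LN": 87.31,  "SIm_CSF": 90.53,   "SIsd_CSF": 27.27},
      "asymmetry_delta": 1.70,
      "asymmetry_delta_sisd": 54.20
    },
    {
      "group_label": "PD",
      "n_subjects": 19,
      "means": {"SL": 7.57, "LL": 16.54, "area": 177.38, "SIm_LN": 801.21, "SIsd_LN": 96.60, "SIm_CSF": 1089.97, "SIsd_CSF": 51.39},
      "sds":   {"SL": 1.84, "LL": 1.66,  "area": 28.31,  "SIm_LN": 397.56, "SIsd_LN": 59.52, "SIm_CSF": 86.48,   "SIsd_CSF": 27.54},
      "asymmetry_delta": 1.06,
      "asymmetry_delta_sisd": 18.10
    },
    {
      "group_label": "CG",
      "n_subjects": 19,
      "means": {"SL": 7.29, "LL": 16.86, "area": 193.42, "SIm_LN": 1048.25, "SIsd_LN": 145.09, "SIm_CSF": 1118.57, "SIsd_CSF": 66.23},
      "sds":   {"SL": 2.17, "LL": 1.61,  "area": 40.23,  "SIm_LN": 410.81,  "SIsd_LN": 75.78,  "SIm_CSF": 100.10,  "SIsd_CSF": 33.24},
      "asymmetry_delta": 0.96,
      "asymmetry_delta_sisd": 21.76
    }
  ]
}
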
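{
  "format": "gadadiscrim-model/1",
  "provenance": "published coefficients of the five-variable GADA+/T2DM discriminant tool (printed report tables; raw canonical weights and group centroids were not published)",
  "variables": ["age_lt30", "age_30to50", "bmi_lt23", "bmi_23to25", "tg_ge_cut", "hba1c_ge_cut", "hdl_ge_cut"],
  "raw_coefficients": null,
  "std_coefficients": {
    "age_lt30": 0.46,
    "age_30to50": 0.36,
    "bmi_lt23": 0.63,
    "bmi_23to25": 0.22,
    "tg_ge_cut": -0.34,
    "hba1c_ge_cut": 0.32,
    "hdl_ge_cut": 0.36
  },
  "loadings": {
    "age_lt30": 0.37,
    "age_30to50": 0.11,
    "bmi_lt23": 0.63,
    "bmi_23to25": -0.11,
    "tg_ge_cut": -0.47,
    "hba1c_ge_cut": 0.30,
    "hdl_ge_cut": 0.43
  },
  "wilks_lambda": 0.475,
  "eigenvalue": 1.106,
  "canonical_correlation": 0.725,
  "wilks_chi2": null,
  "wilks_df": 7,
  "wilks_p": null,
  "priors": {"GADA_POS": 0.5, "T2DM": 0.5},
  "fisher": {
    "GADA_POS": {
      "coefficients": [5.556, 4.274, 6.030, 3.756, 2.525, 2.442, 4.658],
      "constant": -7.917
    },
    "T2DM": {
      "coefficients": [2.208, 2.576, 2.371, 2.421, 4.298, 0.911, 2.808],
      "constant": -3.764
    }
  },
  "cutoffs": {"tg": 98, "hba1c": 8.6, "hdl": 46}
}
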
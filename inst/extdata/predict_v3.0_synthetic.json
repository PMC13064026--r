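{
  "version": "v3.0",
  "description": "SYNTHETIC PREDICT v3.0 coefficient set. The published v3.0 source is not redistributed here; this file carries the v2.x engine skeleton plus the structural additions v3.0 is documented to make -- progesterone-receptor level terms, a smoking term on the other-cause prognostic index, a radiotherapy breast-cancer benefit, a per-Gray mean-heart-dose cardiac harm (larger for smokers), a small chemotherapy other-cause harm, and recalibrated (lower, more contemporary) baseline intercepts. Numeric values for the additions are plausible literature-scale stand-ins, NOT the published v3.0 estimates; replace this file with a transcription of the released algorithm for production use.",
  "supported_age_range": [20, 85],
  "baseline_hazards": {
    "breast": {
      "er_positive": {
        "intercept": 0.5799402,
        "inv_sqrt_time": -7.527762,
        "log_time_over_sqrt_time": -1.812513
      },
      "er_negative": {
        "intercept": -1.2613961,
        "inv_time_sq": 0.4707332,
        "inv_time": -3.51355
      }
    },
    "other": {
      "intercept": -6.052919,
      "log_time": 1.079863,
      "sqrt_time": 0.3255321
    }
  },
  "coefficients": {
    "breast": {
      "er_positive": {
        "age_fp1": 34.53642,
        "age_fp2": -34.20342,
        "size_log": 0.7530729,
        "nodes_log": 0.7060723,
        "grade": 0.746655,
        "screening": -0.22763366,
        "her2_positive": 0.2413,
        "her2_negative": -0.0762,
        "her2_unknown": 0.0,
        "ki67_positive": 0.14904,
        "ki67_negative": -0.11333,
        "ki67_unknown": 0.0,
        "pr_positive": -0.0619,
        "pr_negative": 0.0,
        "pr_unknown": 0.0
      },
      "er_negative": {
        "age_linear": 0.0089827,
        "size_sqrt": 2.093446,
        "nodes_log": 0.6260541,
        "grade_high": 1.129091,
        "her2_positive": 0.2413,
        "her2_negative": -0.0762,
        "her2_unknown": 0.0,
        "pr_positive": -0.2231,
        "pr_negative": 0.0,
        "pr_unknown": 0.0
      }
    },
    "other": {
      "age_sq": 0.0698252,
      "smoker": 0.6931472
    }
  },
  "constants": {
    "er_positive": {
      "age_fp1_center": 0.0287449295,
      "age_fp2_center": 0.0510121013,
      "size_log_center": -1.545233938,
      "nodes_log_center": -1.387566896,
      "grade_center": 0.0
    },
    "er_negative": {
      "age_center": 56.3254902,
      "size_sqrt_center": 0.5090456276,
      "nodes_log_center": -1.086916249
    },
    "other": {
      "age_sq_center": 34.23391957
    },
    "detection_unknown_weight": 0.204,
    "micromets_node_value": 0.5
  },
  "treatment_effects": {
    "breast": {
      "endocrine": -0.3857,
      "chemo_second_gen": -0.248,
      "chemo_third_gen": -0.446,
      "trastuzumab": -0.3567,
      "bisphosphonates": -0.198,
      "radiotherapy": -0.1625189,
      "endocrine_ten_year_extra": {
        "log_hr": -0.26,
        "applies_after_year": 10
      }
    }
  },
  "harms": {
    "heart_dose_per_gy": 0.0417,
    "heart_dose_smoker_multiplier": 2.0,
    "chemo_other": 0.0487902
  }
}
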
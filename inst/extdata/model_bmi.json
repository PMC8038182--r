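{
  "id": "bmi",
  "label": "BMI-based fatty liver prediction model",
  "intercept": -0.533,
  "n": 1672,
  "fit": {"aic": 1746, "bic": 1794, "c_statistic": 0.81, "cox_snell_r2": 0.26, "nagelkerke_r2": 0.35},
  "terms": [
    {"variable": "age", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [-0.137], "ci": [[-0.193, -0.080]], "ci_flag": [null]},
    {"variable": "bmi", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [0.063], "ci": [[0.039, 0.086]], "ci_flag": [null]},
    {"variable": "alt", "type": "fp", "scale": 100, "powers": [-2, -1],
     "coefficients": [0.036, -0.767],
     "ci": [[0.020, 0.052], [-0.943, -0.591]], "ci_flag": [null, null]},
    {"variable": "homa", "type": "fp", "scale": 10, "powers": [1, 2],
     "coefficients": [3.583, -2.634],
     "ci": [[1.775, 5.392], [-4.395, -0.873]], "ci_flag": [null, null]},
    {"variable": "tg", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [0.004], "ci": [[0.001, 0.007]], "ci_flag": [null]},
    {"variable": "ur", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [0.172], "ci": [[0.072, 0.272]], "ci_flag": [null]}
  ]
}
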
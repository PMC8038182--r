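{
  "id": "wc",
  "label": "WC-based fatty liver prediction model",
  "intercept": -0.925,
  "n": 1672,
  "fit": {"aic": 1755, "bic": 1804, "c_statistic": 0.81, "cox_snell_r2": 0.25, "nagelkerke_r2": 0.34},
  "terms": [
    {"variable": "age", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [-0.132], "ci": [[-0.189, 0.075]],
     "ci_flag": ["sign_typo_suspected"]},
    {"variable": "alt", "type": "fp", "scale": 100, "powers": [-2, -1],
     "coefficients": [0.034, -0.728],
     "ci": [[0.018, 0.049], [-0.898, 0.557]],
     "ci_flag": [null, "sign_typo_suspected"]},
    {"variable": "homa", "type": "fp", "scale": 10, "powers": [1, 2],
     "coefficients": [3.848, -2.662],
     "ci": [[2.015, 5.681], [-4.490, 0.834]],
     "ci_flag": [null, "sign_typo_suspected"]},
    {"variable": "tg", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [0.004], "ci": [[0.001, 0.007]], "ci_flag": [null]},
    {"variable": "ur", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [0.171], "ci": [[0.070, 0.271]], "ci_flag": [null]},
    {"variable": "wc", "type": "linear", "scale": 1, "powers": [1],
     "coefficients": [0.022], "ci": [[0.012, 0.032]], "ci_flag": [null]}
  ]
}
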
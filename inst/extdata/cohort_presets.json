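{
  "comment": "Study-emulating synthetic cohort presets. Two groups: non-users show a positive high-minus-low mixing-weight difference (flexible arbitration), users show none; both groups are more risk-sensitive on high stakes, with a smaller user-group high-stakes mu. Effect scales are calibrated so the stakes-by-group interaction on the mixing weight is detected with roughly 80% power at 40 subjects per group.",
  "hybrid": {
    "nonuser": {
      "alpha": {"loc": 0.5, "scale": 0.15, "lower": 0.05, "upper": 0.95},
      "beta": {"loc": 1.0, "scale": 0.3, "lower": 0.3, "upper": 2.5},
      "lam": {"loc": 0.5, "scale": 0.15, "lower": 0.05, "upper": 0.95},
      "w_low": {"loc": 0.35, "scale": 0.12, "lower": 0.02, "upper": 0.98},
      "w_high": {"loc": 0.55, "scale": 0.12, "lower": 0.02, "upper": 0.98},
      "pi": {"loc": 0.1, "scale": 0.1, "lower": -1, "upper": 1},
      "rho": {"loc": 0.0, "scale": 0.1, "lower": -1, "upper": 1}
    },
    "user": {
      "alpha": {"loc": 0.5, "scale": 0.15, "lower": 0.05, "upper": 0.95},
      "beta": {"loc": 1.0, "scale": 0.3, "lower": 0.3, "upper": 2.5},
      "lam": {"loc": 0.5, "scale": 0.15, "lower": 0.05, "upper": 0.95},
      "w_low": {"loc": 0.45, "scale": 0.12, "lower": 0.02, "upper": 0.98},
      "w_high": {"loc": 0.45, "scale": 0.12, "lower": 0.02, "upper": 0.98},
      "pi": {"loc": 0.1, "scale": 0.1, "lower": -1, "upper": 1},
      "rho": {"loc": 0.0, "scale": 0.1, "lower": -1, "upper": 1}
    }
  },
  "utility": {
    "nonuser": {
      "mu_low": {"loc": 0.2, "scale": 0.2, "lower": -2, "upper": 2},
      "mu_high": {"loc": 0.8, "scale": 0.2, "lower": -2, "upper": 2},
      "beta_u": {"loc": 1.0, "scale": 0.3, "lower": 0.2, "upper": 3},
      "eta": {"loc": 0.3, "scale": 0.1, "lower": 0.05, "upper": 0.9},
      "gamma_disc": {"loc": 0.9, "scale": 0.05, "lower": 0.5, "upper": 1},
      "delta_limit": {"loc": 3.0, "scale": 1.0, "lower": 0.5, "upper": 8}
    },
    "user": {
      "mu_low": {"loc": 0.3, "scale": 0.2, "lower": -2, "upper": 2},
      "mu_high": {"loc": 0.5, "scale": 0.2, "lower": -2, "upper": 2},
      "beta_u": {"loc": 1.0, "scale": 0.3, "lower": 0.2, "upper": 3},
      "eta": {"loc": 0.3, "scale": 0.1, "lower": 0.05, "upper": 0.9},
      "gamma_disc": {"loc": 0.9, "scale": 0.05, "lower": 0.5, "upper": 1},
      "delta_limit": {"loc": 3.0, "scale": 1.0, "lower": 0.5, "upper": 8}
    }
  },
  "severity": {
    "nonuser": {"loc": 1.0, "scale": 0.5, "lower": 0, "upper": 40},
    "user": {"loc": 8.5, "scale": 4.0, "lower": 0, "upper": 40}
  }
}
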
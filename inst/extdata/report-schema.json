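{
  "title": "orbitype pipeline report",
  "required": {
    "meta": {
      "required": {
        "seed": "number",
        "n": "number",
        "folds": "number",
        "bootstrap_B": "number"
      }
    },
    "type_distribution": {
      "required": { "type": "any", "n": "number", "prevalence": "number" }
    },
    "descriptives": {
      "required": {
        "type": "any", "dimension": "any",
        "mean": "number", "sd": "number", "min": "number", "max": "number"
      }
    },
    "group_tests": {
      "required": {
        "dimension": "any", "anova_f": "number", "anova_p": "number",
        "eta_squared": "number", "kw_h": "number", "kw_p": "number"
      }
    },
    "derivation": {
      "required": {
        "cluster_map": "any",
        "cv_accuracy_mean": "number",
        "cv_accuracy_sd": "number"
      }
    },
    "derived_cutoffs": {
      "required": {
        "h_cut": "number", "d_cut": "number",
        "d1": "number", "d2": "number",
        "stump_training_accuracy": "number",
        "depth_training_accuracy": "number"
      }
    },
    "full_rule": {
      "required": { "accuracy": "number", "precision": "any", "recall": "any" }
    },
    "depth_rule": {
      "required": { "accuracy": "number", "precision": "any", "recall": "any" }
    }
  }
}
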
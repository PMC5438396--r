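{
  "rules": [
    {
      "conditions": [
        {"feature": "rh-inferiorparietal-roughness", "op": "le", "threshold": 0.666},
        {"feature": "lh-lateraloccipital-roughness", "op": "le", "threshold": 0.609}
      ],
      "predicted_class": "control",
      "coverage": {"control": 9, "ET": 0}
    },
    {
      "conditions": [
        {"feature": "rh-fusiform-roughness", "op": "le", "threshold": 0.696}
      ],
      "predicted_class": "ET",
      "coverage": {"control": 0, "ET": 12}
    },
    {
      "conditions": [
        {"feature": "lh-medialorbitofrontal-roughness", "op": "le", "threshold": 0.841},
        {"feature": "lh-frontal-lobe-roughness", "op": "gt", "threshold": 0.558}
      ],
      "predicted_class": "control",
      "coverage": {"control": 8, "ET": 0}
    },
    {
      "conditions": [
        {"feature": "lh-parstriangularis-roughness", "op": "gt", "threshold": 0.514}
      ],
      "predicted_class": "ET",
      "coverage": {"control": 0, "ET": 6}
    },
    {
      "conditions": [],
      "predicted_class": "control",
      "coverage": {"control": 1, "ET": 0}
    }
  ],
  "metadata": {
    "source": "published descriptive model fit on the original cohort (no train/test split)",
    "note": "coverage counts refer to the original (unavailable) cohort and are informational only"
  }
}
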
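{
  "name": "von_kodolitsch",
  "label": "Von Kodolitsch decision tool",
  "aggregation": "count_categories",
  "high_risk_threshold": 1,
  "comparator": ">=",
  "provisional": false,
  "items": [
    {"name": "aortic_pain", "category": "aortic_pain", "predicate": "abrupt_onset_pain & (tearing_ripping | migrating_radiating)"},
    {"name": "mediastinal_widening_cxr", "category": "cxr", "predicate": "cxr_abnormal"},
    {"name": "pulse_or_bp_differential", "category": "pulse_differential", "predicate": "pulse_deficit | bp_differential_gt20"}
  ]
}
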
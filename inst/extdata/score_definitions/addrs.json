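{
  "name": "addrs",
  "label": "Aortic dissection detection risk score (ADD-RS)",
  "aggregation": "count_categories",
  "high_risk_threshold": 1,
  "comparator": ">=",
  "provisional": false,
  "items": [
    {"name": "connective_tissue_disease", "category": "predisposing", "predicate": "connective_tissue_disease"},
    {"name": "family_history_aortic_disease", "category": "predisposing", "predicate": "family_history"},
    {"name": "known_aortic_valve_disease", "category": "predisposing", "predicate": "aortic_valve_disease"},
    {"name": "recent_aortic_manipulation", "category": "predisposing", "predicate": "aortic_manipulation"},
    {"name": "known_thoracic_aortic_aneurysm", "category": "predisposing", "predicate": "known_thoracic_aortic_aneurysm"},
    {"name": "abrupt_onset_pain", "category": "pain", "predicate": "abrupt_onset_pain"},
    {"name": "severe_pain", "category": "pain", "predicate": "severe_pain"},
    {"name": "ripping_tearing_pain", "category": "pain", "predicate": "tearing_ripping"},
    {"name": "perfusion_deficit", "category": "exam", "predicate": "pulse_deficit | bp_differential_gt20"},
    {"name": "focal_neurological_deficit", "category": "exam", "predicate": "focal_neuro_deficit"},
    {"name": "new_aortic_insufficiency_murmur", "category": "exam", "predicate": "new_murmur"},
    {"name": "hypotension_or_shock", "category": "exam", "predicate": "hypotension"}
  ]
}
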
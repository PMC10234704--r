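{
  "name": "ripp_engine",
  "label": "RIPP score (engine encoding; equivalence check against the native scorer)",
  "aggregation": "sum_points",
  "high_risk_threshold": 1,
  "comparator": ">=",
  "provisional": false,
  "items": [
    {"name": "aortic_aneurysm", "points": 2, "predicate": "known_aortic_aneurysm | known_thoracic_aortic_aneurysm"},
    {"name": "nonaneurysmal_risk_factor", "points": 1, "predicate": "(family_history | aortic_manipulation | aortic_valve_disease | connective_tissue_disease) & !(known_aortic_aneurysm | known_thoracic_aortic_aneurysm)"},
    {"name": "impression_alternative_likely", "points": -1, "predicate": "impression == 'alternative_likely'"},
    {"name": "impression_aas_most_likely", "points": 2, "predicate": "impression == 'aas_most_likely'"},
    {"name": "any_exam_finding", "points": 2, "predicate": "hypotension | new_murmur | pulse_deficit | focal_neuro_deficit | bp_differential_gt20"},
    {"name": "any_pain_feature", "points": 1, "predicate": "abrupt_onset_pain | tearing_ripping | migrating_radiating | severe_pain"},
    {"name": "three_or_more_pain_features", "points": 1, "predicate": "(abrupt_onset_pain & tearing_ripping & migrating_radiating) | (abrupt_onset_pain & tearing_ripping & severe_pain) | (abrupt_onset_pain & migrating_radiating & severe_pain) | (tearing_ripping & migrating_radiating & severe_pain)"}
  ]
}
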
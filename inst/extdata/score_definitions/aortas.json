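{
  "name": "aortas",
  "label": "AORTAs score (provisional encoding, synthetic transcription)",
  "aggregation": "sum_points",
  "high_risk_threshold": 2,
  "comparator": ">=",
  "provisional": true,
  "comment": "Item list and weights transcribed provisionally from secondary descriptions of the AORTAs rule; the validation study cites but does not restate them. Edit this file to substitute the authoritative encoding.",
  "items": [
    {"name": "known_aneurysm", "points": 1, "predicate": "known_aortic_aneurysm | known_thoracic_aortic_aneurysm"},
    {"name": "hypotension_or_shock", "points": 2, "predicate": "hypotension"},
    {"name": "ripping_tearing_pain", "points": 1, "predicate": "tearing_ripping"},
    {"name": "abrupt_onset_pain", "points": 1, "predicate": "abrupt_onset_pain"},
    {"name": "severe_pain", "points": 1, "predicate": "severe_pain"},
    {"name": "neurological_or_pulse_deficit", "points": 1, "predicate": "focal_neuro_deficit | pulse_deficit"}
  ]
}
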
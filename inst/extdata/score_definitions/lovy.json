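{
  "name": "lovy",
  "label": "Lovy clinical decision tool (provisional encoding, synthetic transcription)",
  "aggregation": "count_categories",
  "high_risk_threshold": 2,
  "comparator": ">=",
  "provisional": true,
  "comment": "Item list transcribed provisionally from secondary descriptions of the Lovy predictors; the validation study cites but does not restate them. Edit this file to substitute the authoritative encoding.",
  "items": [
    {"name": "abrupt_onset_pain", "category": "abrupt_onset", "predicate": "abrupt_onset_pain"},
    {"name": "tearing_or_migrating_pain", "category": "pain_quality", "predicate": "tearing_ripping | migrating_radiating"},
    {"name": "known_aneurysm_or_risk_factor", "category": "history", "predicate": "known_aortic_aneurysm | known_thoracic_aortic_aneurysm | connective_tissue_disease | family_history"}
  ]
}
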
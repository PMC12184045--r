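{
  "profile_id": "aur_lecanemab",
  "label": "Lecanemab appropriate use recommendations - best-effort stand-in",
  "amyloid_mode": "pet_equivalent",
  "tau_rule_enabled": false,
  "provenance": "Mappable subset of the lecanemab AUR, which largely adopt the CLARITY-AD selection criteria with added safety exclusions.",
  "inclusion_rules": [
    {"rule_id": "age_window", "field_path": "age_years",
     "predicate": {"type": "range", "lo": 50, "hi": 90},
     "provenance": "AUR age guidance"},
    {"rule_id": "mmse_window", "field_path": "mmse",
     "predicate": {"type": "range", "lo": 22, "hi": 30},
     "provenance": "AUR MMSE >= 22"},
    {"rule_id": "cdr_stage", "field_path": "cdr_global",
     "predicate": {"type": "in_set", "values": [0.5, 1]},
     "provenance": "AUR: MCI or mild dementia, CDR 0.5 or 1"},
    {"rule_id": "memory_box", "field_path": "cdr_memory_box",
     "predicate": {"type": "range", "lo": 0.5, "hi": 3},
     "provenance": "memory box >= 0.5"}
  ],
  "exclusion_rules": [
    {"rule_id": "no_stroke_tia", "field_path": "comorbidity_flags.stroke_or_tia",
     "predicate": {"type": "flag_false"},
     "provenance": "cerebrovascular event exclusion"},
    {"rule_id": "no_seizures", "field_path": "comorbidity_flags.seizures",
     "predicate": {"type": "flag_false"},
     "provenance": "seizure disorder exclusion"},
    {"rule_id": "no_bleeding_disorder", "field_path": "comorbidity_flags.bleeding_disorder",
     "predicate": {"type": "flag_false"},
     "provenance": "bleeding-risk exclusion"},
    {"rule_id": "no_unstable_psychiatric", "field_path": "comorbidity_flags.unstable_psychiatric",
     "predicate": {"type": "flag_false"},
     "provenance": "unstable psychiatric illness exclusion"},
    {"rule_id": "no_active_cancer", "field_path": "comorbidity_flags.cancer_active",
     "predicate": {"type": "flag_false"},
     "provenance": "active malignancy exclusion"},
    {"rule_id": "no_anticoagulants", "field_path": "medication_flags.anticoagulant_use",
     "predicate": {"type": "flag_false"},
     "provenance": "AUR safety exclusion: anticoagulation"}
  ]
}
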
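{
  "_comment": "Illustrative codebook for a NACC-style export. Documentation only: column names and missing codes must be checked against the data dictionary of the actual distribution before use.",
  "missing_token": "",
  "strict_fields": ["participant_id"],
  "clinical": {
    "column_map": {
      "participant_id": "NACCID",
      "age_years": "NACCAGE",
      "mmse": "NACCMMSE",
      "cdr_global": "CDRGLOB",
      "cdr_memory_box": "MEMORY",
      "etiologic_ad_dx": "PROBAD"
    },
    "value_map": {
      "mmse": {"88": "missing", "95": "missing", "96": "missing", "97": "missing", "98": "missing", "-4": "missing"},
      "etiologic_ad_dx": {"1": "TRUE", "0": "FALSE", "8": "missing", "9": "missing"}
    }
  },
  "neuropath": {
    "column_map": {
      "participant_id": "NACCID",
      "thal_phase": "NPTHAL",
      "braak_stage": "NACCBRAA",
      "cerad_score": "NACCNEUR"
    },
    "value_map": {
      "thal_phase": {"7": "missing", "8": "missing", "9": "missing"},
      "braak_stage": {"7": "missing", "8": "missing", "9": "missing"},
      "cerad_score": {"7": "missing", "8": "missing", "9": "missing"}
    }
  }
}
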
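{
  "type": "object",
  "required": ["report_type", "patient_id", "ttd_min", "truncated", "ischemia",
               "organ_flags", "content_hash"],
  "properties": {
    "report_type": {"type": "string", "enum": ["post_wlsm"]},
    "patient_id": {"type": "string"},
    "wlsm_time_min": {"type": "number", "minimum": 0},
    "ttd_min": {"type": "number", "minimum": 0},
    "truncated": {"type": "boolean"},
    "complete": {"type": "boolean"},
    "ischemia": {"type": "array"},
    "organ_flags": {"type": "object"},
    "organ_windows_min": {"type": "object"},
    "withdrawal_details": {"type": "string"},
    "content_hash": {"type": "string"}
  }
}
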
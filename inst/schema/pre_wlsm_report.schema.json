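{
  "type": "object",
  "required": ["report_type", "patient_id", "headline", "probability_table", "content_hash"],
  "properties": {
    "report_type": {"type": "string", "enum": ["pre_wlsm"]},
    "patient_id": {"type": "string"},
    "assessed_at": {"type": "string"},
    "headline": {
      "type": "object",
      "required": ["variant", "p30", "p60", "p120"],
      "properties": {
        "variant": {"type": "string",
                    "enum": ["variability", "clinical", "physician", "combined"]},
        "p30": {"type": "number", "minimum": 0, "maximum": 1},
        "p60": {"type": "number", "minimum": 0, "maximum": 1},
        "p120": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "probability_table": {"type": "object"},
    "data_quality": {"type": "object"},
    "content_hash": {"type": "string"}
  }
}
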
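{
  "title": "afwear run report",
  "description": "Required structure of report.json written by run_report(). Field lists are checked by validate_report().",
  "required": ["seed", "cohort", "interpretable_time", "activity", "methods"],
  "interpretable_time_required": [
    "n", "n_meets_80", "pct_meets_80", "pooled_recording_h",
    "pooled_interpretable_h", "pooled_fraction_pct"
  ]
}
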
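{
  "title": "continuitest results JSON",
  "description": "Structured output written by write_results(): per-population fit and continuity-test results with run configuration and site-filter accounting.",
  "required_top_level": {
    "results": "array of per-population result rows",
    "config": "object: run configuration and seeds",
    "filters": "object: per-population site-filter counts"
  },
  "required_row_fields": [
    "pop", "cov", "t1", "t2", "eps", "lnL",
    "t1_cont", "lnL_cont", "lrt", "p_chi2_1df", "p_mixture", "status"
  ]
}
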
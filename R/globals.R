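# data.table non-standard evaluation columns
utils::globalVariables(c(
  "finding_id", "age", "risk_score", "imputed", "a1", "a2", "s1", "s2",
  "k", "j", "N", "from", "to", "patient", "interval", "offset",
  "cancer", "p_cancer", ".N", ".SD"
))
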
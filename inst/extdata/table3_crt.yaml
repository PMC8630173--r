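# CRT super-responder cohort, count column of the published baseline table.
# The printed Strauss definition count (32) exceeds the printed sex-specific
# QRSD count (31), which no conjunctive reading of the Strauss rule can
# satisfy; that definition row is therefore omitted here (the remaining
# counts are jointly satisfiable).
label: crt
n: 33
sex:
  M: 17
  F: 16
constraints:
- predicate: qrsd_ge_120
  count: 33
- predicate: qrsd_ge_130
  count: 32
- predicate: sex_qrsd_cutoff
  count: 31
- predicate: v1_qs_rs
  count: 33
- predicate: no_q_v56
  count: 33
- predicate: notch_lateral_or
  count: 33
- predicate: notch_lateral_all
  count: 25
- predicate: notch_ge2_any6
  count: 32
- predicate: esc2013
  count: 33
- predicate: aha2009
  count: 11
- predicate: aha2009_qV56I_norwpt
  count: 23
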
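# Matched non-procedure-induced LBBB control cohort, count column of the
# published definition-feature table; sex split from the clinical table.
label: control
n: 118
sex:
  M: 50
  F: 68
constraints:
- predicate: qrsd_ge_120
  count: 118
- predicate: qrsd_ge_130
  count: 101
- predicate: sex_qrsd_cutoff
  count: 95
- predicate: v1_qs_rs
  count: 118
- predicate: no_q_v56
  count: 118
- predicate: no_q_v56_i
  count: 111
- predicate: no_q_v56_i_avl
  count: 92
- predicate: q_aVL
  count: 26
- predicate: rwpt_gt60_v56
  count: 20
- predicate: rwpt_gt60_v6_only
  count: 60
- predicate: notch_lateral_or
  count: 100
- predicate: notch_lateral_all
  count: 37
- predicate: notch_ge2_any6
  count: 93
- predicate: esc2013
  count: 100
- predicate: strauss
  count: 80
- predicate: aha2009
  count: 8
- predicate: aha2009_qV56I_rwpt
  count: 8
- predicate: aha2009_qV56IaVL_rwpt
  count: 8
- predicate: aha2009_qV56I_norwpt
  count: 37
- predicate: aha2009_qV56IaVL_norwpt
  count: 35
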
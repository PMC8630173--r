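# Procedure-induced (aortic-valve-implantation) LBBB cohort, count column of
# the published definition-feature table; sex split from the clinical table.
label: avi
n: 59
sex:
  M: 25
  F: 34
constraints:
- predicate: qrsd_ge_120
  count: 59
- predicate: qrsd_ge_130
  count: 58
- predicate: sex_qrsd_cutoff
  count: 56
- predicate: v1_qs_rs
  count: 59
- predicate: no_q_v56
  count: 59
- predicate: no_q_v56_i
  count: 57
- predicate: no_q_v56_i_avl
  count: 50
- predicate: q_aVL
  count: 9
- predicate: rwpt_gt60_v56
  count: 16
- predicate: rwpt_gt60_v6_only
  count: 30
- predicate: notch_lateral_or
  count: 59
- predicate: notch_lateral_all
  count: 32
- predicate: notch_ge2_any6
  count: 59
- predicate: esc2013
  count: 59
- predicate: strauss
  count: 56
- predicate: aha2009
  count: 10
- predicate: aha2009_qV56I_rwpt
  count: 10
- predicate: aha2009_qV56IaVL_rwpt
  count: 10
- predicate: aha2009_qV56I_norwpt
  count: 31
- predicate: aha2009_qV56IaVL_norwpt
  count: 28
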
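name: esc2013
qrsd_rule: fixed_120
v1_rule: qs_or_rs_required
q_forbidden_leads:
- V5
- V6
notch_lead_set:
- I
- aVL
- V5
- V6
notch_min_count: 1
rwpt_required: no
axis_ancillary: no
axis_threshold_deg: 30.0
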
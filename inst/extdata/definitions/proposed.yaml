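name: proposed
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
notch_min_count: 2
rwpt_required: no
axis_ancillary: yes
axis_threshold_deg: 30.0
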
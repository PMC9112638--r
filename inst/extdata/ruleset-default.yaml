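# Default surveillance rule set, hand-transcribed from the CAG colonoscopy
# surveillance recommendations, with USMSTF 2020 filling the gaps CAG does
# not address (post-CRC-resection sequence, second-surveillance grid).
# Intervals are [min, max] in months. Predicates are conjunctions over the
# derived findings features; numeric conditions are closed ranges.
name: cag-usmstf-default
version: 1
index_rules:
  - id: no_polyps
    months: [120, 120]
    when: {n_groups: [0, 0]}
  - id: ta_1_2_lt10
    months: [84, 120]
    when: {adenoma_count: [1, 2], adenoma_max_size: [1, 9]}
  - id: ta_3_4_lt10
    months: [36, 60]
    when: {adenoma_count: [3, 4], adenoma_max_size: [1, 9]}
  - id: adenoma_5_10
    months: [36, 36]
    when: {adenoma_count: [5, 10]}
  - id: adenoma_ge10mm
    months: [36, 36]
    when: {adenoma_max_size: [10, .inf]}
  - id: villous_any
    months: [36, 36]
    when: {villous_present: true}
  - id: hgd_any
    months: [36, 36]
    when: {hgd_present: true}
  - id: adenoma_gt10
    months: [12, 12]
    when: {adenoma_count: [11, .inf]}
  - id: ssp_1_2_lt10
    months: [60, 120]
    when: {serrated_count: [1, 2], serrated_max_size: [1, 9]}
  - id: ssp_3_4_lt10
    months: [36, 60]
    when: {serrated_count: [3, 4], serrated_max_size: [1, 9]}
  - id: ssp_5_10
    months: [36, 36]
    when: {serrated_count: [5, .inf]}
  - id: ssp_ge10mm
    months: [36, 36]
    when: {serrated_max_size: [10, .inf]}
  - id: ssp_dysplasia
    months: [36, 36]
    when: {ssp_dysplasia_present: true}
  - id: tsa_any
    months: [36, 36]
    when: {tsa_present: true}
  - id: hp_ge10mm
    months: [36, 60]
    when: {hp_max_size: [10, .inf]}
  - id: hp_rectosigmoid_lt10
    months: [120, 120]
    when: {hp_rectosigmoid_max_size: [1, 9]}
  - id: hp_proximal_lt10
    months: [60, 120]
    when: {hp_proximal_max_size: [1, 9]}
  - id: piecemeal_ge20mm
    months: [6, 6]
    when: {piecemeal_ge20: true}
surveillance_step:
  NORMAL:    {NORMAL: [120, 120], LOW_RISK: [84, 120], HIGH_RISK: [36, 36]}
  LOW_RISK:  {NORMAL: [120, 120], LOW_RISK: [84, 120], HIGH_RISK: [36, 36]}
  HIGH_RISK: {NORMAL: [60, 60],   LOW_RISK: [60, 60],  HIGH_RISK: [36, 36]}
post_crc_sequence:
  "0": [12, 12]
  "1": [36, 36]
  "2plus": [60, 60]
family_history_rules:
  high_risk_cap_months: 60
  low_risk_cap_months: 120
options:
  # high-risk prior-exam definition used by the surveillance step grid
  high_risk:
    adenoma_min_size: 10
    adenoma_min_count: 5
    serrated_min_size: 10
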
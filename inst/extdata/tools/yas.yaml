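# Synthetic placeholder tool: grouped four-step checklist in the style of the
# Yorkshire Ambulance Service major trauma tool. Thresholds are conventional
# field-triage values, NOT the deployed service document.
service: YAS
grouped: true
steps:
- index: 1
  label: physiology
  mandatory: true
  criteria:
  - {variable: sbp,  comparator: "<",  threshold: 90, sustained: false, description: systolic hypotension}
  - {variable: gcs,  comparator: "<=", threshold: 12, sustained: false, description: reduced conscious level}
  - {variable: rr,   comparator: "<",  threshold: 10, sustained: false, description: bradypnoea}
  - {variable: rr,   comparator: ">",  threshold: 29, sustained: false, description: tachypnoea}
  - {variable: spo2, comparator: "<",  threshold: 90, sustained: true,  description: sustained hypoxia}
- index: 2
  label: anatomy
  mandatory: true
  criteria:
  - variable: injury_pattern
    comparator: in
    threshold: [penetrating_torso, penetrating_head_neck, open_fracture]
    sustained: false
    description: significant anatomical injury
- index: 3
  label: mechanism
  mandatory: false
  criteria:
  - variable: mechanism
    comparator: in
    threshold: [fall_gt_1m, rta_motorcycle, rta_pedestrian]
    sustained: false
    description: high-risk mechanism of injury
- index: 4
  label: special_circumstances
  mandatory: false
  criteria:
  - {variable: age, comparator: ">=", threshold: 65, sustained: false, description: older adult}
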
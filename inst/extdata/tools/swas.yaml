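# Synthetic placeholder tool: ungrouped single-checklist tool in the style of
# the South Western Ambulance Service trauma triage tool. Thresholds are
# conventional field-triage values, NOT the deployed service document.
service: SWAS
grouped: false
steps:
- index: 1
  label: ungrouped
  mandatory: true
  criteria:
  - {variable: sbp, comparator: "<",  threshold: 90, sustained: true,  description: sustained systolic hypotension}
  - {variable: gcs, comparator: "<=", threshold: 8,  sustained: false, description: severely reduced conscious level}
  - {variable: rr,  comparator: "<",  threshold: 8,  sustained: false, description: severe bradypnoea}
  - {variable: rr,  comparator: ">",  threshold: 35, sustained: false, description: severe tachypnoea}
  - variable: injury_pattern
    comparator: in
    threshold: [penetrating_torso]
    sustained: false
    description: penetrating torso injury
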
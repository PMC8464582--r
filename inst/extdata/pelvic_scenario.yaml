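schema_version: 1
scenario_id: pelvic_trauma_default
profile:
  sex: male
  age: 34
  injured_region: pelvis
initial_vitals:
  heart_rate: 110.0
  systolic_bp: 100.0
  diastolic_bp: 65.0
  spo2: 93.0
  respiratory_rate: 22.0
  temperature: 34.5
  consciousness: 13.0
remaining_lifetime: 240.0
catalog_id: default
lethal_bounds:
  heart_rate:
  - 20.0
  - 220.0
  systolic_bp:
  - 60.0
  - 260.0
  diastolic_bp:
  - 25.0
  - 160.0
  spo2:
  - 70.0
  - .inf
  respiratory_rate:
  - 4.0
  - 40.0
  temperature:
  - 30.0
  - 41.0
  consciousness:
  - 2.5
  - 16.0

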
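scenario:
  name: setpoint_load_event
  setpoint_profile:
    time:
    - 0.0
    - 40.0
    - 60.0
    value:
    - 95.0
    - 80.0
    - 95.0
  cylinder_tau: 0.5
  condition: infected
  input_delay: 0.3
  intermediate_delay: 0.0
  gas_model_variant: canonical
  controller:
    type: sfpimrac
  duration: 120.0
  dt: 0.001
  reference_drive: command

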
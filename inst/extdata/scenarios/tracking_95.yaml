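scenario:
  name: tracking_95
  setpoint_profile:
    time: 0.0
    value: 95.0
  cylinder_tau: 0.5
  condition: infected
  input_delay: 0.0
  intermediate_delay: 0.0
  gas_model_variant: canonical
  controller:
    type: sfpimrac
  duration: 60.0
  dt: 0.001
  reference_drive: command

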
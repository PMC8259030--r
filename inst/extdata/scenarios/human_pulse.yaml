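# 48-h neutral-colon lactose pulse demonstrating the full switch cycle
setting: in_vivo
initial_pH: 7.0
initial_lactose: 0
duration_h: 48
sampling_interval_h: 0.5
env_preset: human_colon
preculture_pH: 7.0
arms: [test]
bolus:
  - {time_h: 2.0, lactose_mM: 30.0}
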
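# 6-h murine colon simulation; gavage 12 mg lactose / 20 g body weight
# mapped to 87.6 mM over a 0.4 mL lumen volume
setting: in_vivo
initial_pH: 5.0
initial_lactose: 0
duration_h: 6
sampling_interval_h: 0.25
env_preset: mouse_colon
arms: [control]
bolus:
  - {time_h: 0.0, lactose_mM: 87.6}
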
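# 12-h culture simulation at adjusted initial pH (1% lactose ~= 29.2 mM)
setting: in_vitro
initial_pH: 5.34
initial_lactose: 29.2
duration_h: 12
sampling_interval_h: 0.5
env_preset: in_vitro
preculture_pH: 7.0
arms: [test, control]
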
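kind: transport_scenario
true_slope_pH_s: 0.0005
drift_slope_pH_s: -0.0001
light_on_s: 60.0
light_off_s: 120.0
duration_s: 180.0
sample_interval_s: 1.0
noise_sigma: 0.0002
relax_tau_s: 30.0
seed: 1
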
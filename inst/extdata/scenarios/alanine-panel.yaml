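kind: panel_scenario
mutant_names:
- WT
- K33A
- H124A
- R146A
- K147A
- K157A
- K158A
- R161A
- K162A
- R71A
- H167A
- K205A
- H217A
true_activity_cl:
- 0.0005
- 0.00025
- 0.000475
- 0.000525
- 0.00045
- 0.00055
- 0.000425
- 0.0005
- 0.000475
- 0.000325
- 0.000165
- 4.5e-05
- 4.5e-04
true_activity_so4:
- 0.0005
- 0.00025
- 0.00045
- 0.00055
- 0.000425
- 0.000525
- 0.0004
- 0.000475
- 0.0005
- 4.0e-05
- 1.5e-04
- 4.5e-05
- 4.75e-04
expression:
- 1.0
- 0.5
- 1.0
- 1.0
- 1.0
- 1.0
- 1.0
- 1.0
- 1.0
- 1.0
- 1.0
- 1.0
- 1.0
n_replicates: 4
replicate_cv: 0.1
seed: 1
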
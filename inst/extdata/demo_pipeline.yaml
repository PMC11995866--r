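# Demo pipeline: one chloride titration, one wild-type photocycle, one
# mutant activity panel. Run with:
#   run_pipeline(system.file("extdata", "demo_pipeline.yaml",
#                            package = "halopump"), out_dir)
datasets:
- name: wt_cl_titration
  scenario: WT-Cl
  analysis: binding
  model: auto
  seed: 1
- name: wt_nacl_photocycle
  scenario: WT-NaCl-photocycle
  analysis: photocycle
  n_exp: 3
  seed: 1
- name: alanine_panel
  scenario: alanine-panel
  analysis: transport-panel
  seed: 1
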
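# Example study manifest for stratadjust-cli.R / read_manifest().
# `defaults` are scenario_config() arguments shared by all scenarios;
# each entry under `scenarios` overrides them.
defaults:
  "n": 200
  n_reps: 1000
methods: [none, categories, linear, fp2, rcs5]
root_seed: 2026
output_dir: study-output
scenarios:
  - {shape: linear, strength: strong, beta1: 0.0}
  - {shape: linear, strength: strong, beta1: 0.4}
  - {shape: exponential, strength: strong, beta1: 0.4}
  - {shape: quadratic, strength: strong, beta1: 0.4, missingness: mar30}
  - {shape: linear, strength: strong, beta1: 0.4, beta2: 0.0, beta3: 0.78,
     missingness: mar30, scenario_id: interaction-strong-mar30}
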
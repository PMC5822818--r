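# Example run configuration for inst/scripts/run_pipeline.R.
# Unspecified fields use the package defaults (pipeline_config()).
n_lesions: 16
tasks:
- ki67
effect_map:
  ki67:
    ktrans: 1.6
class_balance: 0.5
noise_sd: 0.02
k: 10
max_order: 4
n_boot: 50
template_args:
  grid_shape: [14, 14, 14]
  spacing: [2.0, 2.0, 2.0]
  lesion_radius: 7.0
seed: 1
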
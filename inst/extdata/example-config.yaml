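# Example run configuration: the nest preset with a reduced training
# schedule.  Any omitted key takes the preset default.
preset: nest
model:
  alpha: 1.0
training:
  trials_per_word: 300
  stim_steps: 16
  stsi_epsilon: 0.5
evaluation:
  trials_per_port: 3
seed: 1
output_dir: runs/example
verbosity: 1
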
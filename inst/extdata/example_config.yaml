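# Example analysis configuration for `sedisloc analyze` / cliAnalyze().
# Paths are relative to the working directory.
dataset: scene/dataset
output_dir: scene/analysis
line:
  - [132, 296]    # (x, y) in nm, scan frame
  - [372, 158]
cell: p-terphenyl
zone: [0, 0, 1]
aperture_radius: 0.02
sample_fraction: 0.05
seed: 7
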
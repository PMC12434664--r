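# Toy-hairpin demo configuration: morph ensemble with a scripted ion bridge
# across the stem termini, all analysis stages enabled. Any key omitted here
# falls back to the package defaults (see default_config()).
seed: 1
out_dir: results/demo
structure:
  synthetic: hairpin
  annotations: synthetic
ensemble:
  kind: morph
  n_frames: 200
  unfold_fraction: 1.0
  noise: 0.3
  n_ions: 8
  box_edge: 150
  bridge:
    pair: [1, 12]
    fraction: 0.7
elvim:
  sigma0: 3
  eps: 0.15
  n_iter: 60
ions:
  cutoff: 8
  q_bin: 0.05
  min_sep: 4
pairs:
  lambda: 1.2
wham:
  k_q: 20
  n_steps: 8000
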
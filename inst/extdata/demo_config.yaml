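# Demo pipeline configuration: a compact end-to-end run (simulate ->
# model RDM -> searchlight + temporal RSA) sized to finish in a few
# minutes on one CPU.
seed: 7
out_dir: results
n_conditions: 12
geometry_dim: 3
glove:
  n_runs: 2
  trials_per_block: 4
  noise_sd: 0.2
  signal_scale: 1
fmri:
  subdivisions: 1
  radius_mm: 8
  n_runs: 4
  noise_sd: 1
  signal_scale: 1
  region_size: 12
  diameter_mm: 10
  n_perm: 300
  alpha: 0.01
meg:
  n_sources: 12
  fs: 250
  trials_per_condition: 20
  band: beta
  window: [-210, -90]
  epoch: [-500, 1500]
  noise_sd: 1
  signal_scale: 1
  n_partitions: 10
  n_perm: 200
  cluster_p: 0.01
  fwe_alpha: 0.005
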
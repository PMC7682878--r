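# Example project configuration: simulate one split-FP transfection plus
# its controls and a 1x/5x tandem-tag imaging experiment, then run both
# analysis pipelines. Any omitted key falls back to the package default.
seed: 2024
output_dir: results
flow_sim:
  n_events: 20000
  kd: 10            # units of the median FP_11 concentration
  expression_ratio: 2
  rho: 0.7
  doublet_fraction: 0.05
  transfected_fraction: 0.8
flow_pipeline:
  retain_fraction: 0.5
  threshold_quantile: 0.999
imaging_sim:
  n_cells: 40
  n_replicates: 4
image_pipeline:
  ball_radius_px: 20
  size_range_um2: [80, 2000]
  circularity_range: [0.1, 1.0]
  condition_folds:
    1x: 1.0
    5x: 2.3
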
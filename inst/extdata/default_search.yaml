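# Default hyperparameter search spaces for the three classifier families.
# Conventional ranges; the tuner draws a random subset first and then runs
# a coordinate grid refinement around the incumbent.

random_forest:
  num_trees: [200, 500, 1000]
  mtry: [4, 8, 12]
  min_node_size: [1, 5, 10]
  max_depth: [0, 12]          # 0 = unlimited

svm:
  cost: [0.5, 1, 4, 16]
  gamma: [0.01, 0.04, 0.1]

mlp:
  size: [16, 32, 64, 128]
  decay: [0.0001, 0.001, 0.01]
  maxit: [300]
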
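{
  "family": "tanh_network",
  "hidden_count": 3,
  "scale": 0.5,
  "hidden_weights": [
    [0.0311, 0.642],
    [-0.5334, -0.0241],
    [0.3507, 0.9401]
  ],
  "hidden_biases": [-1.0617, 1.4045, -0.1777],
  "output_weights": [
    [-23.3637, 0.6636, -24.9085],
    [24.3295, 34.7418, 22.0398],
    [-34.021, -5.4716, 0.7791]
  ],
  "output_biases": [76.8278, -13.0326, 28.5284],
  "responses": ["qL", "qa", "qb"],
  "inputs": ["srs", "lba"]
}
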
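{
  "seed": 42,
  "out": "pipeline-out",
  "sim": { "residual_prob_by_si": [0.8, 0.05, 0] }
}
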
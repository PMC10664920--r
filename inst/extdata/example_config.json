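{
  "command": "classify",
  "seed": 1,
  "network": {
    "family": "single_q",
    "n_layers": 5,
    "parameters": { "q": 3, "w_ff": 0.8, "w_fb": 0.6 }
  },
  "out": "results"
}
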
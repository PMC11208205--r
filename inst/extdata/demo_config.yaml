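landscape:
  synthetic:
    rows: 120
    cols: 120
    seed: 42
scenario: rubber_expansion
iterations: [2, 5, 10]
seed: 42
output_dir: landesca-demo-output
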